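#' Kinetic parameter set on the natural (positive) scale
#'
#' Bundles the strictly positive kinetic parameters of a Hill-kinetics GRN
#' model: per-gene synthesis rates `P` (concentration/time) and degradation
#' rates `S` (1/time), and per-edge thresholds `Q` (concentration) and
#' cooperativity exponents `R` (dimensionless), aligned 1:1 with the edge
#' order of the network.
#'
#' @param P,S numeric vectors of length `N` (genes), strictly positive.
#' @param Q,R numeric vectors of length `M` (edges), strictly positive.
#' @param network optional [grn_network()]; when given, lengths are checked
#'   against it.
#' @return Object of class `grn_params`.
#' @seealso [to_log()], [from_log()]
#' @export
grn_params <- function(P, S, Q = numeric(), R = numeric(), network = NULL) {
  P <- as.numeric(P); S <- as.numeric(S)
  Q <- as.numeric(Q); R <- as.numeric(R)
  if (length(P) != length(S))
    stop("P and S must have one entry per gene", call. = FALSE)
  if (length(Q) != length(R))
    stop("Q and R must have one entry per edge", call. = FALSE)
  vals <- c(P, S, Q, R)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all kinetic parameters must be strictly positive and finite",
         call. = FALSE)
  if (!is.null(network)) {
    stopifnot(inherits(network, "grn_network"))
    if (length(P) != network$n_genes || length(Q) != network$n_edges)
      stop("parameter lengths do not match the network (N = ",
           network$n_genes, ", M = ", network$n_edges, ")", call. = FALSE)
  }
  structure(list(P = P, S = S, Q = Q, R = R), class = "grn_params")
}

#' @export
print.grn_params <- function(x, ...) {
  cat("<grn_params> N = ", length(x$P), " genes, M = ", length(x$Q),
      " edges (", 2 * (length(x$P) + length(x$Q)), " parameters)\n", sep = "")
  invisible(x)
}

#' Log-scale (unconstrained) parameterization
#'
#' The estimation problem is solved on the log scale: `P = exp(p)`,
#' `Q = exp(q)`, `R = exp(r)`, `S = exp(s)`.  Any real-valued log vector
#' maps to a strictly positive parameter set, so the positivity constraint
#' disappears from the optimization.  The coordinates are labelled as
#' belonging to the `theta_p` block (`p`, `q`, `s`) or the `theta_r` block
#' (`r`), the split the alternating scheme estimates one at a time.
#'
#' @param params a [grn_params()] object (all entries > 0).
#' @return `to_log`: object of class `grn_logparams` with elements
#'   `p`, `s`, `q`, `r`.
#' @examples
#' th <- to_log(grn_params(P = 2, S = 0.5))
#' from_log(th)$P   # 2
#' @export
to_log <- function(params) {
  stopifnot(inherits(params, "grn_params"))
  structure(list(p = log(params$P), s = log(params$S),
                 q = log(params$Q), r = log(params$R)),
            class = "grn_logparams")
}

#' @rdname to_log
#' @param logparams a `grn_logparams` object (any real values).
#' @param network optional network for length validation.
#' @export
from_log <- function(logparams, network = NULL) {
  stopifnot(inherits(logparams, "grn_logparams"))
  grn_params(P = exp(logparams$p), S = exp(logparams$s),
             Q = exp(logparams$q), R = exp(logparams$r), network = network)
}

#' @export
print.grn_logparams <- function(x, ...) {
  cat("<grn_logparams> |theta_p| = ", length(x$p) + length(x$q) + length(x$s),
      ", |theta_r| = ", length(x$r), "\n", sep = "")
  invisible(x)
}

#' Construct a log-scale parameter set directly
#'
#' @param p,s per-gene real log-parameters (`P = exp(p)`, `S = exp(s)`).
#' @param q,r per-edge real log-parameters (`Q = exp(q)`, `R = exp(r)`).
#' @return Object of class `grn_logparams`.
#' @export
grn_logparams <- function(p, s, q = numeric(), r = numeric()) {
  stopifnot(length(p) == length(s), length(q) == length(r),
            all(is.finite(c(p, s, q, r))))
  structure(list(p = as.numeric(p), s = as.numeric(s),
                 q = as.numeric(q), r = as.numeric(r)),
            class = "grn_logparams")
}

# Canonical flattening of theta used by the optimizers:
# [p (N), q (M), s (N), r (M)]; theta_p = first M + 2N, theta_r = last M.
theta_flatten <- function(lp) c(lp$p, lp$q, lp$s, lp$r)

theta_unflatten <- function(v, N, M) {
  stopifnot(length(v) == 2 * (N + M))
  grn_logparams(p = v[seq_len(N)],
                q = v[N + seq_len(M)],
                s = v[N + M + seq_len(N)],
                r = v[N + M + N + seq_len(M)])
}

# Logical masks over the flattened vector for the two estimation blocks.
theta_masks <- function(N, M) {
  len <- 2 * (N + M)
  p_mask <- rep(FALSE, len)
  p_mask[seq_len(M + 2 * N)] <- TRUE
  list(theta_p = p_mask, theta_r = !p_mask)
}
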