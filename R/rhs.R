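#' Hill-kinetics ODE right-hand side
#'
#' Evaluates the multiplicative Hill-regulation model
#' `dx_i/dt = P_i * prod_{j in I_i} h^-(x_j, Q_ij, R_ij)
#'                * prod_{k in A_i} h^+(x_k, Q_ik, R_ik) - S_i * x_i`,
#' where `I_i` and `A_i` are the inhibitors and activators of gene `i`.
#' A gene with no regulators has an empty product (= 1), so its production
#' term is the bare constant `P_i`.
#'
#' @param network a [grn_network()].
#' @param params a [grn_params()] aligned with the network.
#' @param x state: numeric vector of length `N`, or a matrix with one row
#'   per state and `N` columns (vectorized evaluation).
#' @return Derivative with the same shape as `x` (concentration/time).
#' @export
grn_rhs <- function(network, params, x) {
  stopifnot(inherits(network, "grn_network"), inherits(params, "grn_params"))
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != network$n_genes)
    stop("state dimension (", ncol(X), ") does not match network (",
         network$n_genes, " genes)", call. = FALSE)
  if (length(params$P) != network$n_genes ||
      length(params$Q) != network$n_edges)
    stop("parameter set does not match network dimensions", call. = FALSE)
  d <- rhs_core(network, params, X)
  colnames(d) <- network$genes
  if (vec) d[1L, ] else d
}

# X: n x N matrix (rows = evaluation points). Returns n x N derivatives.
# States are clamped at 0 inside the Hill factors (spline curves used by
# the estimator may dip slightly negative); the degradation term uses the
# raw state so the map stays smooth in x.
rhs_core <- function(network, params, X) {
  n <- nrow(X)
  N <- network$n_genes
  prod_h <- matrix(1, n, N)
  for (k in seq_len(network$n_edges)) {
    h <- hill_eval(X[, network$reg[k]], params$Q[k], params$R[k],
                   activating = network$sign[k] > 0)
    prod_h[, network$tgt[k]] <- prod_h[, network$tgt[k]] * h
  }
  sweep(prod_h, 2L, params$P, `*`) - sweep(X, 2L, params$S, `*`)
}

# Production term P_i * prod h only (n x N); used by the steady-state map.
rhs_production <- function(network, params, X) {
  n <- nrow(X)
  prod_h <- matrix(1, n, network$n_genes)
  for (k in seq_len(network$n_edges)) {
    h <- hill_eval(X[, network$reg[k]], params$Q[k], params$R[k],
                   activating = network$sign[k] > 0)
    prod_h[, network$tgt[k]] <- prod_h[, network$tgt[k]] * h
  }
  sweep(prod_h, 2L, params$P, `*`)
}

# Jacobian d f_i / d x_j of the right-hand side.
# For a single state vector returns an N x N matrix; for an n x N matrix
# of states returns an n x N x N array (point, i, j).
rhs_jacobian <- function(network, params, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  n <- nrow(X)
  N <- network$n_genes
  M <- network$n_edges
  # Hill factor values per edge (needed to form products-over-others).
  H <- matrix(1, n, max(M, 1L))
  prod_h <- matrix(1, n, N)
  for (k in seq_len(M)) {
    H[, k] <- hill_eval(X[, network$reg[k]], params$Q[k], params$R[k],
                        activating = network$sign[k] > 0)
    prod_h[, network$tgt[k]] <- prod_h[, network$tgt[k]] * H[, k]
  }
  J <- array(0, dim = c(n, N, N))
  for (k in seq_len(M)) {
    i <- network$tgt[k]; j <- network$reg[k]
    dh <- hill_deriv(X[, j], params$Q[k], params$R[k],
                     activating = network$sign[k] > 0)
    # product over the other regulators of i = prod_h / H_k (H_k > 0)
    J[, i, j] <- J[, i, j] + params$P[i] * (prod_h[, i] / H[, k]) * dh
  }
  for (i in seq_len(N)) J[, i, i] <- J[, i, i] - params$S[i]
  if (vec) J[1L, , ] else J
}
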