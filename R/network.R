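#' Gene regulatory network structure
#'
#' A `grn_network` is a directed signed graph: genes are nodes and each edge
#' `(regulator -> target, sign)` states that the regulator's product either
#' activates (`+`) or inhibits (`-`) expression of the target.  Edge order
#' is significant: kinetic parameters `Q[k]`, `R[k]` are keyed to edge `k`.
#'
#' @param genes character vector of unique gene names (state ordering).
#' @param regulator regulator of each edge: gene names or integer indices.
#' @param target target of each edge: gene names or integer indices.
#' @param sign per-edge sign: `"+"`/`"-"` or `+1`/`-1`.
#' @return An object of class `grn_network` with elements `genes`, `reg`,
#'   `tgt` (integer indices), `sign` (`+1`/`-1`), `n_genes`, `n_edges`.
#' @examples
#' net <- grn_network(c("a", "b"), regulator = c("a", "b"),
#'                    target = c("b", "a"), sign = c("+", "-"))
#' parameter_count(net)
#' @export
grn_network <- function(genes, regulator = character(), target = character(),
                        sign = character()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("gene names must be unique", call. = FALSE)
  if (length(genes) == 0L)
    stop("network needs at least one gene", call. = FALSE)
  reg <- resolve_gene(regulator, genes, "regulator")
  tgt <- resolve_gene(target, genes, "target")
  if (length(reg) != length(tgt) || length(reg) != length(sign))
    stop("regulator, target and sign must have equal length", call. = FALSE)
  sgn <- resolve_sign(sign)
  if (anyDuplicated(cbind(reg, tgt)))
    stop("duplicate (regulator, target) edge", call. = FALSE)
  structure(
    list(genes = genes, reg = reg, tgt = tgt, sign = sgn,
         n_genes = length(genes), n_edges = length(reg)),
    class = "grn_network")
}

resolve_gene <- function(x, genes, what) {
  if (is.numeric(x)) {
    idx <- as.integer(x)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > length(genes)))
      stop(what, " index out of range", call. = FALSE)
    return(idx)
  }
  idx <- match(as.character(x), genes)
  if (anyNA(idx))
    stop("unknown ", what, " gene: ",
         paste(unique(x[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}

resolve_sign <- function(sign) {
  if (is.numeric(sign)) {
    if (!all(sign %in% c(-1, 1)))
      stop("numeric sign must be +1 or -1", call. = FALSE)
    return(as.integer(sign))
  }
  s <- as.character(sign)
  bad <- !s %in% c("+", "-")
  if (any(bad))
    stop("unknown edge sign symbol: ", paste(unique(s[bad]), collapse = ", "),
         call. = FALSE)
  ifelse(s == "+", 1L, -1L)
}

#' @export
print.grn_network <- function(x, ...) {
  cat("<grn_network> ", x$n_genes, " genes, ", x$n_edges, " edges\n", sep = "")
  cat("  genes: ", paste(x$genes, collapse = ", "), "\n", sep = "")
  n_act <- sum(x$sign > 0)
  cat("  edges: ", n_act, " activating, ", x$n_edges - n_act,
      " inhibiting\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.grn_network <- function(x, ...) {
  data.frame(regulator = x$genes[x$reg], target = x$genes[x$tgt],
             sign = ifelse(x$sign > 0, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Parameter counts of a Hill-kinetics network model
#'
#' A network with `N` genes and `M` edges needs `2(M + N)` kinetic
#' parameters: synthesis rates `P` and degradation rates `S` (one each per
#' gene), and thresholds `Q` and cooperativity exponents `R` (one each per
#' edge).  The alternating estimation scheme splits the log-scale vector
#' into `theta_p` (`p`, `q`, `s`: `M + 2N` coordinates) and `theta_r`
#' (`r`: `M` coordinates).
#'
#' @param network a [grn_network()].
#' @return Named integer vector `c(total, theta_p, theta_r)`.
#' @export
parameter_count <- function(network) {
  stopifnot(inherits(network, "grn_network"))
  N <- network$n_genes
  M <- network$n_edges
  c(total = 2L * (M + N), theta_p = M + 2L * N, theta_r = M)
}

# Per-target regulator index lists, computed once per estimator run.
incoming_edges <- function(network) {
  split(seq_len(network$n_edges), factor(network$tgt,
                                         levels = seq_len(network$n_genes)))
}
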