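#' Sparse time-series expression data
#'
#' Container for gene-product concentration measurements: observation
#' times `T_E` and a matrix of values `y_i(t)` (one column per gene, `NA`
#' for missing entries).  The experiment window `[t0, tf]` defaults to the
#' observation span and defines the domain of the spline basis used by the
#' estimator.
#'
#' @param times strictly increasing numeric vector of observation times (s).
#' @param values numeric matrix, `length(times)` rows, one column per gene
#'   (column names are gene names); non-negative where present (mM).
#' @param t0,tf experiment window; must contain all observation times.
#' @return Object of class `grn_data` with elements `times`, `values`,
#'   `t0`, `tf`, `genes`.
#' @export
grn_data <- function(times, values, t0 = min(times), tf = max(times)) {
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (length(times) != nrow(values))
    stop("length(times) must equal nrow(values)", call. = FALSE)
  if (length(times) < 2L)
    stop("need at least two observation times", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("observation times must be strictly increasing", call. = FALSE)
  if (t0 > times[1L] || tf < times[length(times)])
    stop("[t0, tf] must contain all observation times", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("observed concentrations must be non-negative", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("g", seq_len(ncol(values)))
  structure(list(times = times, values = values, t0 = t0, tf = tf,
                 genes = colnames(values)),
            class = "grn_data")
}

#' @export
print.grn_data <- function(x, ...) {
  cat("<grn_data> ", length(x$times), " times x ", ncol(x$values),
      " genes over [", format(x$t0), ", ", format(x$tf), "]",
      if (anyNA(x$values)) sprintf(" (%d missing)", sum(is.na(x$values))),
      "\n", sep = "")
  invisible(x)
}

# Align data columns to network gene order; errors on mismatch.
align_data <- function(data, network) {
  stopifnot(inherits(data, "grn_data"), inherits(network, "grn_network"))
  idx <- match(network$genes, data$genes)
  if (anyNA(idx))
    stop("data is missing gene column(s): ",
         paste(network$genes[is.na(idx)], collapse = ", "), call. = FALSE)
  grn_data(data$times, data$values[, idx, drop = FALSE],
           t0 = data$t0, tf = data$tf)
}
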