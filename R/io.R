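#' Read and write network edge lists
#'
#' Tab-separated, three columns `regulator  target  sign` with
#' `sign` one of `+`/`-`.  Lines starting with `#` are comments; an
#' optional `# genes: a b c` header fixes the state ordering, otherwise
#' genes are ordered by first appearance (regulators before targets,
#' line by line).
#'
#' @param path file path.
#' @return `read_network()`: a [grn_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  gene_order <- NULL
  hdr <- grep("^#\\s*genes:", lines, value = TRUE)
  if (length(hdr) >= 1L)
    gene_order <- strsplit(trimws(sub("^#\\s*genes:", "", hdr[1L])),
                           "\\s+")[[1L]]
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  reg <- character(0); tgt <- character(0); sgn <- character(0)
  for (i in body_idx) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) != 3L)
      stop("malformed network line ", i, ": expected 3 fields, got ",
           length(f), " (", lines[i], ")", call. = FALSE)
    if (!f[3L] %in% c("+", "-"))
      stop("unknown sign symbol '", f[3L], "' on line ", i, call. = FALSE)
    reg <- c(reg, f[1L]); tgt <- c(tgt, f[2L]); sgn <- c(sgn, f[3L])
  }
  genes <- if (is.null(gene_order)) {
    unique(as.vector(rbind(reg, tgt)))
  } else gene_order
  grn_network(genes, regulator = reg, target = tgt, sign = sgn)
}

#' @rdname read_network
#' @param network a [grn_network()].
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "grn_network"))
  df <- as.data.frame(network)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("# genes:", paste(network$genes, collapse = " ")), con)
  writeLines(paste(df$regulator, df$target, df$sign, sep = "\t"), con)
  invisible(path)
}

#' Read and write kinetic parameter files
#'
#' Flat JSON with arrays `P`, `S` (per gene) and `Q`, `R` (per edge, in
#' edge order).  The log-scale dialect uses the same keys prefixed
#' `log_` and round-trips a `grn_logparams`.
#'
#' @param path file path.
#' @param network optional network for length validation.
#' @return `read_params()`: a [grn_params()] or (log dialect)
#'   `grn_logparams`.
#' @export
read_params <- function(path, network = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (all(c("P", "S") %in% names(obj))) {
    unknown <- setdiff(names(obj), c("P", "S", "Q", "R"))
    if (length(unknown))
      stop("unknown key(s) in parameter file: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    return(grn_params(P = obj$P, S = obj$S,
                      Q = obj$Q %||% numeric(), R = obj$R %||% numeric(),
                      network = network))
  }
  if (all(c("log_P", "log_S") %in% names(obj))) {
    return(grn_logparams(p = obj$log_P, s = obj$log_S,
                         q = obj$log_Q %||% numeric(),
                         r = obj$log_R %||% numeric()))
  }
  stop("parameter file must contain P/S/Q/R or log_P/log_S/log_Q/log_R",
       call. = FALSE)
}

#' @rdname read_params
#' @param params a [grn_params()] or `grn_logparams`.
#' @export
write_params <- function(params, path) {
  obj <- if (inherits(params, "grn_params")) {
    list(P = params$P, S = params$S, Q = params$Q, R = params$R)
  } else if (inherits(params, "grn_logparams")) {
    list(log_P = params$p, log_S = params$s, log_Q = params$q,
         log_R = params$r)
  } else stop("expected grn_params or grn_logparams", call. = FALSE)
  jsonlite::write_json(obj, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and write time-series data
#'
#' CSV with header `time,<gene1>,<gene2>,...`; empty cells are missing
#' observations.  Values are written at full precision so reruns can be
#' compared bit for bit.
#'
#' @param path file path.
#' @param t0,tf optional experiment window override.
#' @return `read_timeseries()`: a [grn_data()].
#' @export
read_timeseries <- function(path, t0 = NULL, tf = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "time")
    stop("time-series file must have a leading 'time' column", call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  grn_data(df$time, vals,
           t0 = t0 %||% min(df$time), tf = tf %||% max(df$time))
}

#' @rdname read_timeseries
#' @param data a [grn_data()].
#' @export
write_timeseries <- function(data, path) {
  stopifnot(inherits(data, "grn_data"))
  df <- data.frame(time = fmt_num(data$times), check.names = FALSE)
  for (g in colnames(data$values)) {
    v <- fmt_num(data$values[, g])
    v[is.na(data$values[, g])] <- ""
    df[[g]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write run configuration
#'
#' JSON (a YAML subset) mirroring the fields of [gpm_config()] plus the
#' alternating-loop settings `r_init`, `r_init_scale`, `tol`, `max_loops`
#' and an optional `seed`.  Unknown keys are rejected.
#'
#' @param path file path.
#' @return `read_config()`: list with elements `gpm` (a [gpm_config()])
#'   and `loop` (alternating-loop settings).
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gpm_keys <- names(formals(gpm_config))
  loop_keys <- c("r_init", "r_init_scale", "tol", "max_loops", "seed")
  unknown <- setdiff(names(obj), c(gpm_keys, loop_keys))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- do.call(gpm_config, obj[intersect(names(obj), gpm_keys)])
  loop <- obj[intersect(names(obj), loop_keys)]
  list(gpm = cfg, loop = loop)
}

#' @rdname read_config
#' @param config a [gpm_config()].
#' @param loop named list of alternating-loop settings.
#' @export
write_config <- function(config, path, loop = list()) {
  stopifnot(inherits(config, "gpm_config"))
  jsonlite::write_json(c(unclass(config), loop), path, digits = NA,
                       pretty = TRUE, auto_unbox = TRUE)
  invisible(path)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 12, scientific = FALSE)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
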