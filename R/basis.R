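#' B-spline basis system for trajectory representation
#'
#' Constructs a clamped B-spline basis `phi(t)` on `[t0, tf]` used to
#' represent each gene's trajectory as `x_i(t) = c_i' phi(t)`.  `knots` is
#' the number of breakpoints (joints) including the two endpoints, placed
#' uniformly; with polynomial order `k` (order = degree + 1) the basis
#' dimension is `knots + order - 2`.
#'
#' @param t0,tf domain endpoints, `t0 < tf`.
#' @param order polynomial order (default 4, i.e. cubic pieces).
#' @param knots number of uniform breakpoints including endpoints
#'   (default 100, i.e. 102 basis functions at order 4).
#' @return Object of class `spline_basis` with elements `t0`, `tf`,
#'   `order`, `knots`, `breaks`, `full_knots`, `dim`.
#' @export
spline_basis <- function(t0, tf, order = 4L, knots = 100L) {
  stopifnot(is.finite(t0), is.finite(tf), t0 < tf,
            order >= 1L, knots >= 2L)
  order <- as.integer(order); knots <- as.integer(knots)
  breaks <- seq(t0, tf, length.out = knots)
  full <- c(rep(t0, order - 1L), breaks, rep(tf, order - 1L))
  structure(list(t0 = t0, tf = tf, order = order, knots = knots,
                 breaks = breaks, full_knots = full,
                 dim = knots + order - 2L),
            class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("<spline_basis> order ", x$order, ", ", x$knots, " breakpoints on [",
      format(x$t0), ", ", format(x$tf), "], dim ", x$dim, "\n", sep = "")
  invisible(x)
}

#' Evaluate the basis or its derivative
#'
#' Returns the design matrix of basis values `phi(t)` (or derivatives
#' `phi'(t)`), one row per time point, one column per basis function.
#' Basis rows sum to 1 (partition of unity); derivative rows sum to 0.
#'
#' @param basis a [spline_basis()].
#' @param t numeric vector of times inside `[t0, tf]`.
#' @return Matrix of dimension `length(t) x basis$dim`.
#' @export
eval_basis <- function(basis, t) {
  basis_design(basis, t, deriv = 0L)
}

#' @rdname eval_basis
#' @export
eval_basis_deriv <- function(basis, t) {
  basis_design(basis, t, deriv = 1L)
}

basis_design <- function(basis, t, deriv) {
  stopifnot(inherits(basis, "spline_basis"))
  t <- as.numeric(t)
  eps <- 1e-9 * (basis$tf - basis$t0)
  if (any(t < basis$t0 - eps) || any(t > basis$tf + eps))
    stop("evaluation time outside the basis domain [",
         format(basis$t0), ", ", format(basis$tf), "]", call. = FALSE)
  t <- pmin(pmax(t, basis$t0), basis$tf)
  splines::splineDesign(basis$full_knots, t, ord = basis$order,
                        derivs = rep(deriv, length(t)))
}

#' Quadrature grid for the ODE-fidelity penalty integral
#'
#' Composite Gauss-Legendre rule with `points_per_interval` nodes on each
#' inter-breakpoint interval of the basis.  Exact for polynomials of degree
#' `2 * points_per_interval - 1` per interval, hence exact for the
#' spline-polynomial part of the penalty integrand at the default settings.
#'
#' @param basis a [spline_basis()].
#' @param points_per_interval nodes per interval (default 5).
#' @return List with `times` and `weights`; weights sum to `tf - t0`.
#' @export
quadrature_grid <- function(basis, points_per_interval = 5L) {
  stopifnot(inherits(basis, "spline_basis"), points_per_interval >= 1L)
  gl <- gauss_legendre(as.integer(points_per_interval))
  br <- basis$breaks
  times <- c(); weights <- c()
  for (j in seq_len(length(br) - 1L)) {
    a <- br[j]; b <- br[j + 1L]
    if (b <= a) next
    times <- c(times, (a + b) / 2 + (b - a) / 2 * gl$nodes)
    weights <- c(weights, (b - a) / 2 * gl$weights)
  }
  list(times = times, weights = weights)
}

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch.
gauss_legendre <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1L, ord]^2)
}

#' Penalized least-squares spline smoothing of the data
#'
#' Per-gene linear ridge fit minimizing
#' `sum_t (y_i(t) - c_i' phi(t))^2 + ridge * ||c_i||^2`, used to
#' initialize the inner profiling optimization.  The small default ridge
#' makes the fit unique when there are more basis functions than samples
#' (the usual sparse-data regime); it is never used inside the profiling
#' objectives themselves.
#'
#' @param basis a [spline_basis()].
#' @param data a [grn_data()] whose window matches the basis domain.
#' @param ridge non-negative ridge weight (default `1e-8`).
#' @return Coefficient matrix (`basis$dim` rows, one column per gene).
#' @export
smoothing_fit <- function(basis, data, ridge = 1e-8) {
  stopifnot(inherits(basis, "spline_basis"), inherits(data, "grn_data"),
            ridge >= 0)
  Phi <- eval_basis(basis, data$times)
  K <- basis$dim
  C <- matrix(0, K, ncol(data$values),
              dimnames = list(NULL, colnames(data$values)))
  for (i in seq_len(ncol(data$values))) {
    y <- data$values[, i]
    ok <- !is.na(y)
    if (!any(ok))
      stop("gene ", colnames(data$values)[i], " has no observations",
           call. = FALSE)
    X <- Phi[ok, , drop = FALSE]
    A <- crossprod(X) + diag(ridge, K)
    C[, i] <- solve(A, crossprod(X, y[ok]))
  }
  C
}
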