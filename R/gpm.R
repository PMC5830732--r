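#' Configuration for the generalized profiling estimator
#'
#' Collects the tunable settings of the two-level (profiled) estimator:
#' the ODE-fidelity penalty weight `lambda` (a scalar or one value per
#' gene; default 150), the B-spline basis (`order` 4, `knots` 100
#' breakpoints), the penalty-integral quadrature density, and solver
#' tolerances for the inner (spline-coefficient) and outer (parameter)
#' optimizations.
#'
#' @param lambda penalty weight(s) `lambda_i > 0` (default 150).
#' @param order,knots B-spline settings, see [spline_basis()].
#' @param quad_points Gauss-Legendre nodes per inter-knot interval.
#' @param ridge ridge used only by the [smoothing_fit()] initializer.
#' @param inner_tol,inner_maxit inner Levenberg-Marquardt stopping rule
#'   (relative objective change; iteration cap).
#' @param outer_tol,outer_maxit outer stopping rule (relative objective
#'   change; residual-function evaluation cap).
#' @param fd_step relative forward-difference step for outer gradients
#'   (used when `gradient = "fd"`).
#' @param gradient outer-gradient method: `"cascade"` (default; analytic
#'   implicit-function Jacobian of the profiled residuals, Gauss-Newton
#'   approximation of the inner Hessian) or `"fd"` (forward finite
#'   differences with warm-started inner re-solves).
#' @return Object of class `gpm_config`.
#' @export
gpm_config <- function(lambda = 150, order = 4L, knots = 100L,
                       quad_points = 5L, ridge = 1e-8,
                       inner_tol = 1e-8, inner_maxit = 200L,
                       outer_tol = 1e-8, outer_maxit = 400L,
                       fd_step = 1e-6, gradient = c("cascade", "fd")) {
  gradient <- match.arg(gradient)
  stopifnot(all(lambda > 0), order >= 1, knots >= 2, quad_points >= 1,
            ridge >= 0, inner_tol > 0, inner_maxit >= 1,
            outer_tol > 0, outer_maxit >= 1, fd_step > 0)
  structure(list(lambda = as.numeric(lambda), order = as.integer(order),
                 knots = as.integer(knots),
                 quad_points = as.integer(quad_points), ridge = ridge,
                 inner_tol = inner_tol, inner_maxit = as.integer(inner_maxit),
                 outer_tol = outer_tol, outer_maxit = as.integer(outer_maxit),
                 fd_step = fd_step, gradient = gradient),
            class = "gpm_config")
}

#' @export
print.gpm_config <- function(x, ...) {
  cat("<gpm_config> lambda = ", paste(format(x$lambda), collapse = "/"),
      ", basis order ", x$order, " with ", x$knots, " knots, ",
      x$quad_points, " quadrature points/interval\n", sep = "")
  invisible(x)
}

# Precomputed design matrices shared by all objective evaluations.
gpm_workspace <- function(network, data, config, basis = NULL) {
  data <- align_data(data, network)
  if (is.null(basis))
    basis <- spline_basis(data$t0, data$tf, order = config$order,
                          knots = config$knots)
  N <- network$n_genes
  lambda <- rep_len(config$lambda, N)
  quad <- quadrature_grid(basis, config$quad_points)
  obs_mask <- !is.na(data$values)
  list(network = network, data = data, basis = basis, lambda = lambda,
       N = N, K = basis$dim,
       Phi_obs = eval_basis(basis, data$times),
       obs_mask = obs_mask,
       quad = quad,
       Phi_q = eval_basis(basis, quad$times),
       Phidot_q = eval_basis_deriv(basis, quad$times),
       sqrt_w = sqrt(quad$weights))
}

coef_matrix <- function(coefs, ws) {
  C <- if (is.null(dim(coefs))) matrix(coefs, ws$K, ws$N) else as.matrix(coefs)
  stopifnot(nrow(C) == ws$K, ncol(C) == ws$N)
  C
}

# Explicit partial derivatives of the inner residual vector with respect
# to the flattened log-parameters [p, q, s, r] (free columns only).  Only
# the penalty rows depend on theta explicitly:
#   d r_pen(i,.) / d theta_m = -sqrt(lambda_i w) * d f_i / d theta_m.
# On the log scale, d f_i/d p_i = production_i, d f_i/d s_i = -S_i x_i,
# and for edge k = (j -> i):  d h^+/d q_k = -R u (1 - u),
# d h^+/d r_k = R u (1 - u) log(x_j / Q_k)  (signs flipped for h^-),
# with u = (x/Q)^R / (1 + (x/Q)^R).
inner_theta_jacobian <- function(C, params, ws, free_mask) {
  N <- ws$N; K <- ws$K
  net <- ws$network
  M <- net$n_edges
  nq <- length(ws$quad$times)
  n_data <- sum(ws$obs_mask)
  X_q <- ws$Phi_q %*% C
  PH <- rhs_production(net, params, X_q)      # P_i * prod h, nq x N
  cols <- which(free_mask)
  B <- matrix(0, n_data + nq * N, length(cols))
  sw <- sweep(matrix(ws$sqrt_w, nq, N), 2L, sqrt(ws$lambda), `*`)
  pen_rows <- function(i) n_data + (i - 1L) * nq + seq_len(nq)
  for (ci in seq_along(cols)) {
    m <- cols[ci]
    if (m <= N) {                       # p_i
      i <- m
      dfi <- PH[, i]
    } else if (m <= N + M) {            # q_k
      k <- m - N
      i <- net$tgt[k]
      x <- pmax(X_q[, net$reg[k]], 0)
      u <- hill_saturation(x, params$Q[k], params$R[k])
      h <- if (net$sign[k] > 0) 1 + u else 1 - u
      dh <- params$R[k] * u * (1 - u) * (if (net$sign[k] > 0) -1 else 1)
      dfi <- PH[, i] / h * dh
    } else if (m <= 2 * N + M) {        # s_i
      i <- m - N - M
      dfi <- -params$S[i] * X_q[, i]
    } else {                            # r_k
      k <- m - 2L * N - M
      i <- net$tgt[k]
      x <- pmax(X_q[, net$reg[k]], 0)
      u <- hill_saturation(x, params$Q[k], params$R[k])
      h <- if (net$sign[k] > 0) 1 + u else 1 - u
      L <- ifelse(x > 0, log(x) - log(params$Q[k]), 0)
      dh <- params$R[k] * u * (1 - u) * L * (if (net$sign[k] > 0) 1 else -1)
      dfi <- PH[, i] / h * dh
    }
    B[pen_rows(i), ci] <- -sw[, i] * dfi
  }
  B
}

# Analytic Jacobian of the profiled data residuals with respect to the
# free log-parameters (parameter cascading / implicit function theorem,
# Gauss-Newton approximation of the inner Hessian):
#   d chat/d theta = -(Jc' Jc)^{-1} Jc' B,   J_outer = -Phi_blk d chat/d theta.
profiled_jacobian <- function(C, params, ws, free_mask) {
  Jc <- inner_jacobian(C, params, ws)
  B <- inner_theta_jacobian(C, params, ws, free_mask)
  A <- crossprod(Jc)
  diag(A) <- diag(A) + 1e-10 * max(diag(A))
  X <- solve(A, crossprod(Jc, B))          # = -d chat/d theta
  N <- ws$N; K <- ws$K
  n_data <- sum(ws$obs_mask)
  Jout <- matrix(0, n_data, ncol(B))
  row0 <- 0L
  for (i in seq_len(N)) {
    ok <- ws$obs_mask[, i]
    ni <- sum(ok)
    if (ni > 0)
      Jout[row0 + seq_len(ni), ] <-
        ws$Phi_obs[ok, , drop = FALSE] %*% X[(i - 1L) * K + seq_len(K), ,
                                             drop = FALSE]
    row0 <- row0 + ni
  }
  Jout
}

# Stacked residual vector of the inner problem:
# [per-gene data residuals at observed times;
#  per-gene sqrt(lambda_i w_k) * (c_i' phidot(t_k) - f_i(x(t_k), theta))].
inner_residuals <- function(C, params, ws) {
  fit_obs <- ws$Phi_obs %*% C
  r_data <- (ws$data$values - fit_obs)[ws$obs_mask]
  X_q <- ws$Phi_q %*% C
  dX_q <- ws$Phidot_q %*% C
  F_q <- rhs_core(ws$network, params, X_q)
  r_pen <- sweep(dX_q - F_q, 1L, ws$sqrt_w, `*`)
  r_pen <- sweep(r_pen, 2L, sqrt(ws$lambda), `*`)
  c(r_data, as.vector(r_pen))
}

# Analytic Jacobian of inner_residuals with respect to vec(C).
inner_jacobian <- function(C, params, ws) {
  N <- ws$N; K <- ws$K
  nq <- length(ws$quad$times)
  n_data <- sum(ws$obs_mask)
  X_q <- ws$Phi_q %*% C
  dF <- rhs_jacobian(ws$network, params, X_q)  # nq x N x N
  J <- matrix(0, n_data + nq * N, N * K)
  # data block: residual rows are column-major over the obs_mask matrix,
  # i.e. grouped by gene in gene order.
  row0 <- 0L
  for (i in seq_len(N)) {
    ok <- ws$obs_mask[, i]
    ni <- sum(ok)
    if (ni > 0)
      J[row0 + seq_len(ni), (i - 1L) * K + seq_len(K)] <-
        -ws$Phi_obs[ok, , drop = FALSE]
    row0 <- row0 + ni
  }
  # penalty blocks
  for (i in seq_len(N)) {
    rows <- n_data + (i - 1L) * nq + seq_len(nq)
    sw <- sqrt(ws$lambda[i]) * ws$sqrt_w
    cols_i <- (i - 1L) * K + seq_len(K)
    J[rows, cols_i] <- sw * ws$Phidot_q
    for (j in seq_len(N)) {
      dij <- dF[, i, j]
      if (all(dij == 0)) next
      cols_j <- (j - 1L) * K + seq_len(K)
      J[rows, cols_j] <- J[rows, cols_j] - (sw * dij) * ws$Phi_q
    }
  }
  J
}

#' Inner profiling objective
#'
#' The penalized smoothing criterion minimized over the spline
#' coefficients for fixed log-parameters `theta`:
#' `sum_{t in T_E} sum_i (y_i(t) - c_i' phi(t))^2
#'  + sum_i lambda_i * integral (c_i' phi'(t) - f_i(x(t), theta))^2 dt`,
#' the integral evaluated on the Gauss-Legendre grid of
#' [quadrature_grid()].  Missing observations contribute no data residual.
#'
#' @param coefs coefficient matrix (`basis dim x N`) or stacked vector.
#' @param logparams a `grn_logparams` (mapped through [from_log()]).
#' @param data a [grn_data()].
#' @param network a [grn_network()].
#' @param basis optional [spline_basis()]; defaults to the config's basis
#'   on the data window.
#' @param config a [gpm_config()].
#' @return Non-negative scalar with attributes `data_term` and
#'   `penalty_term`.
#' @export
inner_objective <- function(coefs, logparams, data, network,
                            basis = NULL, config = gpm_config()) {
  ws <- gpm_workspace(network, data, config, basis)
  C <- coef_matrix(coefs, ws)
  params <- from_log(logparams, network)
  r <- inner_residuals(C, params, ws)
  n_data <- sum(ws$obs_mask)
  val <- sum(r^2)
  structure(val,
            data_term = sum(r[seq_len(n_data)]^2),
            penalty_term = val - sum(r[seq_len(n_data)]^2))
}

#' Solve the inner profiling problem
#'
#' Gauss-Newton/Levenberg-Marquardt minimization of [inner_objective()]
#' over the stacked spline coefficients, with an analytic residual
#' Jacobian.  Warm-started from `coefs_init` (default: the
#' [smoothing_fit()] ridge fit of the data).
#'
#' @inheritParams inner_objective
#' @param coefs_init optional initial coefficient matrix.
#' @return List with `coefs` (matrix), `objective` (inner criterion at the
#'   solution), `data_term`, `penalty_term`, `converged`, `iterations`,
#'   `grad_norm`, `message`.
#' @export
inner_solve <- function(logparams, data, network, basis = NULL,
                        config = gpm_config(), coefs_init = NULL) {
  ws <- gpm_workspace(network, data, config, basis)
  inner_solve_ws(logparams, ws, config, coefs_init)
}

inner_solve_ws <- function(logparams, ws, config, coefs_init = NULL) {
  params <- from_log(logparams, ws$network)
  C0 <- if (is.null(coefs_init))
    smoothing_fit(ws$basis, ws$data, ridge = config$ridge)
  else coef_matrix(coefs_init, ws)
  fit <- lm_least_squares(
    fn = function(v) inner_residuals(matrix(v, ws$K, ws$N), params, ws),
    jac = function(v) inner_jacobian(matrix(v, ws$K, ws$N), params, ws),
    x0 = as.vector(C0),
    maxit = config$inner_maxit, ftol = config$inner_tol)
  C <- matrix(fit$par, ws$K, ws$N, dimnames = list(NULL, ws$network$genes))
  r <- inner_residuals(C, params, ws)
  n_data <- sum(ws$obs_mask)
  list(coefs = C,
       objective = sum(r^2),
       data_term = sum(r[seq_len(n_data)]^2),
       penalty_term = sum(r[-seq_len(n_data)]^2),
       converged = fit$converged, iterations = fit$iterations,
       grad_norm = fit$grad_norm, message = fit$message)
}

# Data residual vector (observed entries only) at the profiled coefficients.
profiled_residuals <- function(logparams, ws, config, coefs_init = NULL) {
  sol <- inner_solve_ws(logparams, ws, config, coefs_init)
  fit_obs <- ws$Phi_obs %*% sol$coefs
  list(residuals = (ws$data$values - fit_obs)[ws$obs_mask], solution = sol)
}

#' Outer (profiled) data-fit objective
#'
#' Solves the inner problem for the given log-parameters and returns the
#' plain sum of squared data residuals
#' `sum_{t in T_E} sum_i (y_i(t) - chat_i(theta)' phi(t))^2`, an implicit
#' function of the ODE parameters.
#'
#' @inheritParams inner_solve
#' @return Non-negative scalar with attribute `inner` (the inner-solve
#'   diagnostics, including the profiled coefficients).
#' @export
outer_objective <- function(logparams, data, network, basis = NULL,
                            config = gpm_config(), coefs_init = NULL) {
  ws <- gpm_workspace(network, data, config, basis)
  pr <- profiled_residuals(logparams, ws, config, coefs_init)
  structure(sum(pr$residuals^2), inner = pr$solution)
}

#' Outer parameter optimization over a free coordinate block
#'
#' Unconstrained Levenberg-Marquardt minimization of the profiled data
#' residuals over a selected subset of the flattened log-parameter vector
#' `[p, q, s, r]`; the remaining coordinates stay frozen.  This is the
#' block solver used twice per loop by [alternate_estimate()].  Gradients
#' are forward finite differences of the profiled residuals; every
#' evaluation re-solves the inner problem warm-started from the best
#' coefficients seen so far.  Because only strictly decreasing steps are
#' accepted, the returned objective never exceeds the initial one, and the
#' natural-scale parameters `exp(theta)` are positive by construction.
#'
#' @param theta_init a `grn_logparams` starting point.
#' @param free_mask `"theta_p"`, `"theta_r"`, or a logical vector over the
#'   flattened `[p, q, s, r]` coordinates selecting what to optimize.
#' @inheritParams inner_solve
#' @return List with `theta` (a `grn_logparams`), `objective`,
#'   `objective_init`, `coefs` (profiled coefficients at the solution),
#'   `converged`, `iterations`, `fev`, `message`.
#' @export
outer_solve <- function(theta_init, free_mask, data, network, basis = NULL,
                        config = gpm_config(), coefs_init = NULL) {
  stopifnot(inherits(theta_init, "grn_logparams"))
  ws <- gpm_workspace(network, data, config, basis)
  N <- ws$N; M <- network$n_edges
  masks <- theta_masks(N, M)
  if (is.character(free_mask)) {
    free_mask <- match.arg(free_mask, c("theta_p", "theta_r"))
    free_mask <- masks[[free_mask]]
  }
  free_mask <- as.logical(free_mask)
  stopifnot(length(free_mask) == 2 * (N + M))
  theta0 <- theta_flatten(theta_init)

  warm <- new.env(parent = emptyenv())
  warm$coefs <- coefs_init
  warm$n_resid <- sum(ws$obs_mask)
  # A trial step may push exp(theta) past floating-point range or make the
  # inner problem fail; such points get a huge finite residual so the
  # monotone LM acceptance rule simply rejects them.
  resid_fn <- function(free_vals) {
    th <- theta0
    th[free_mask] <- free_vals
    pr <- tryCatch({
      lp <- theta_unflatten(th, N, M)
      profiled_residuals(lp, ws, config, warm$coefs)
    }, error = function(e) NULL)
    if (is.null(pr) || any(!is.finite(pr$residuals)))
      return(rep(1e150, warm$n_resid))
    obj <- sum(pr$residuals^2)
    if (is.null(warm$first)) warm$first <- obj
    if (is.null(warm$best) || obj <= warm$best) {
      warm$best <- obj
      warm$coefs <- pr$solution$coefs
    }
    pr$residuals
  }

  if (!any(free_mask)) {
    pr <- profiled_residuals(theta_init, ws, config, coefs_init)
    return(list(theta = theta_init, objective = sum(pr$residuals^2),
                objective_init = sum(pr$residuals^2),
                coefs = pr$solution$coefs, converged = TRUE,
                iterations = 0L, fev = 1L,
                message = "empty free set; nothing to optimize"))
  }

  jac_fn <- NULL
  if (identical(config$gradient, "cascade")) {
    jac_fn <- function(free_vals) {
      th <- theta0
      th[free_mask] <- free_vals
      lp <- theta_unflatten(th, N, M)
      params <- from_log(lp)
      sol <- inner_solve_ws(lp, ws, config, warm$coefs)
      warm$coefs <- sol$coefs
      profiled_jacobian(sol$coefs, params, ws, free_mask)
    }
  }

  fit <- lm_least_squares(
    fn = resid_fn, x0 = theta0[free_mask], jac = jac_fn,
    maxit = config$outer_maxit, ftol = config$outer_tol,
    fd_step = config$fd_step, max_fev = config$outer_maxit)
  if (!is.finite(fit$objective))
    stop("outer objective became non-finite", call. = FALSE)
  th <- theta0
  th[free_mask] <- fit$par
  theta_hat <- theta_unflatten(th, N, M)
  pr <- profiled_residuals(theta_hat, ws, config, warm$coefs)
  list(theta = theta_hat, objective = sum(pr$residuals^2),
       objective_init = warm$first,
       coefs = pr$solution$coefs,
       converged = fit$converged, iterations = fit$iterations,
       fev = fit$fev, message = fit$message)
}
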