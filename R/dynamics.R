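#' Forward simulation of the Hill-kinetics ODE system
#'
#' Integrates [grn_rhs()] with an adaptive embedded Runge-Kutta method
#' (Dormand-Prince 5(4)) and returns the solution at the requested output
#' times.  Steps are capped so that every output time is hit exactly.
#' Tiny negative excursions (at the integrator tolerance) are clipped to 0
#' in the returned states only, never inside the solver steps.
#'
#' @param network a [grn_network()].
#' @param params a [grn_params()].
#' @param x0 non-negative initial state vector (length `N`).
#' @param t_span `c(t0, tf)` integration window.
#' @param grid output times (default: 201 equally spaced points).
#' @param rtol,atol relative/absolute local error tolerances.
#' @param max_steps safety cap on accepted steps.
#' @return Object of class `grn_trajectory`: list with `times` and
#'   `states` (matrix, one row per time, columns named by gene).
#' @export
simulate_grn <- function(network, params, x0, t_span, grid = NULL,
                         rtol = 1e-8, atol = 1e-10, max_steps = 1e7) {
  stopifnot(inherits(network, "grn_network"), inherits(params, "grn_params"),
            length(x0) == network$n_genes, all(x0 >= 0),
            length(t_span) == 2L, t_span[2] > t_span[1])
  if (is.null(grid)) grid <- seq(t_span[1], t_span[2], length.out = 201L)
  grid <- sort(unique(as.numeric(grid)))
  if (grid[1] < t_span[1] || grid[length(grid)] > t_span[2])
    stop("output grid must lie inside t_span", call. = FALSE)
  f <- function(x) drop(rhs_core(network, params, matrix(x, nrow = 1L)))
  out <- rk45(f, as.numeric(x0), t_span, grid, rtol, atol, max_steps)
  colnames(out$states) <- network$genes
  out$states[out$states < 0 & out$states > -10 * atol] <- 0
  structure(list(times = out$times, states = out$states),
            class = "grn_trajectory")
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat("<grn_trajectory> ", length(x$times), " time points x ",
      ncol(x$states), " genes over [", format(min(x$times)), ", ",
      format(max(x$times)), "]\n", sep = "")
  invisible(x)
}

# Dormand-Prince RK5(4) with PI-free step control (standard safety 0.9).
rk45 <- function(f, x0, t_span, grid, rtol, atol, max_steps) {
  A <- list(
    c(1/5),
    c(3/40, 9/40),
    c(44/45, -56/15, 32/9),
    c(19372/6561, -25360/2187, 64448/6561, -212/729),
    c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
    c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
  b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
  b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
  t <- t_span[1]; x <- x0
  tf <- t_span[2]
  out <- matrix(NA_real_, length(grid), length(x0))
  gi <- 1L
  if (abs(grid[1] - t) < 1e-14 * max(1, abs(t))) {
    out[1L, ] <- x; gi <- 2L
  }
  k1 <- f(x)
  h <- min((tf - t) / 100, 0.1 * (tf - t) + 1e-12)
  steps <- 0L
  while (t < tf - 1e-14 * max(1, abs(tf))) {
    steps <- steps + 1L
    if (steps > max_steps)
      stop("integrator exceeded max_steps at t = ", format(t),
           " (state = ", paste(format(x, digits = 4), collapse = ", "), ")",
           call. = FALSE)
    h <- min(h, tf - t)
    if (gi <= length(grid)) h <- min(h, grid[gi] - t)
    ks <- matrix(0, length(x), 7L)
    ks[, 1L] <- k1
    for (s in 1:6) {
      xi <- x + h * as.vector(ks[, seq_len(s), drop = FALSE] %*% A[[s]])
      ks[, s + 1L] <- f(xi)
    }
    x5 <- x + h * as.vector(ks %*% b5)
    x4 <- x + h * as.vector(ks %*% b4)
    sc <- atol + rtol * pmax(abs(x), abs(x5))
    err <- sqrt(mean(((x5 - x4) / sc)^2))
    if (!is.finite(err)) err <- 2
    if (err <= 1) {
      t <- t + h
      x <- x5
      k1 <- ks[, 7L]  # FSAL
      while (gi <= length(grid) && grid[gi] <= t + 1e-12 * max(1, abs(t))) {
        out[gi, ] <- x
        gi <- gi + 1L
      }
    }
    fac <- if (err > 0) 0.9 * err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
    if (h <= .Machine$double.eps * max(1, abs(t)))
      stop("integrator step size underflow at t = ", format(t), call. = FALSE)
  }
  if (gi <= length(grid)) out[gi:length(grid), ] <- rep(x, each = length(grid) - gi + 1L)
  list(times = grid, states = out)
}

#' Steady state of the Hill-kinetics model
#'
#' Solves the fixed-point system obtained from the ODE at equilibrium,
#' `x_i = (P_i / S_i) * prod_j h(x_j, Q, R)`, by damped fixed-point
#' iteration `x <- (1 - alpha) x + alpha G(x)` with a Newton fallback on
#' the residual `x - G(x)` (analytic Jacobian).  The map `G` is bounded
#' (each component lies in `(0, 2^{|A_i|} P_i / S_i]`), which makes the
#' damped iteration robust; multiple fixed points are possible, so the
#' result depends on `x_guess` and the guess used should be reported.
#'
#' @param network a [grn_network()].
#' @param params a [grn_params()].
#' @param x_guess strictly positive starting state.
#' @param alpha damping factor in (0, 1].
#' @param tol relative residual tolerance `||x - G(x)||_inf < tol ||x||_inf`.
#' @param maxit damped-iteration cap before the Newton fallback.
#' @return Steady-state vector (named by gene) with attributes `residual`,
#'   `iterations` and `method`.
#' @export
steady_state <- function(network, params, x_guess, alpha = 0.5,
                         tol = 1e-8, maxit = 500L) {
  stopifnot(inherits(network, "grn_network"), inherits(params, "grn_params"),
            length(x_guess) == network$n_genes, all(x_guess > 0))
  G <- function(x) {
    drop(rhs_production(network, params, matrix(x, nrow = 1L))) / params$S
  }
  x <- as.numeric(x_guess)
  res <- Inf
  for (it in seq_len(maxit)) {
    gx <- G(x)
    res <- max(abs(x - gx)) / max(abs(x))
    if (res < tol) break
    x <- (1 - alpha) * x + alpha * gx
  }
  method <- "damped fixed-point"
  if (res >= tol) {
    # Newton on F(x) = x - G(x); dG/dx = (1/S_i) d(production)_i/dx_j,
    # i.e. J_F = -J_rhs / S (the rhs Jacobian includes the -S_i x_i term).
    method <- "newton fallback"
    for (it2 in seq_len(50L)) {
      gx <- G(x)
      Fx <- x - gx
      res <- max(abs(Fx)) / max(abs(x))
      if (res < tol) break
      Jr <- rhs_jacobian(network, params, x)
      JF <- -sweep(Jr, 1L, params$S, `/`)
      step <- tryCatch(solve(JF, Fx), error = function(e) NULL)
      if (is.null(step)) break
      xn <- x - step
      xn[xn < 0] <- 1e-12 * max(abs(x))
      x <- xn
      it <- it + 1L
    }
    if (res >= tol)
      stop("steady-state solver did not converge (best residual ",
           format(res), "); best iterate: ",
           paste(format(x, digits = 6), collapse = ", "), call. = FALSE)
  }
  names(x) <- network$genes
  structure(x, residual = res, iterations = it, method = method)
}

#' Sum of squared errors between steady-state vectors
#'
#' The validation statistic `sum_i (reference_i - model_i)^2` comparing a
#' model's steady state against reference (e.g. experimental) values.
#'
#' @param model_ss,reference numeric vectors of equal length (mM).
#' @return Non-negative scalar (mM^2).
#' @export
steady_state_sse <- function(model_ss, reference) {
  if (length(model_ss) != length(reference))
    stop("steady-state vectors have different lengths", call. = FALSE)
  sum((as.numeric(reference) - as.numeric(model_ss))^2)
}
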