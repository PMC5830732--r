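# Levenberg-Marquardt nonlinear least squares on a residual vector.
#
# Minimizes 0.5 * ||fn(x)||^2 without bound constraints (the package
# removes positivity constraints by working on the log-parameter scale).
# `jac` returns the residual Jacobian; if NULL, forward finite differences
# with relative step `fd_step` are used.  Only strictly decreasing steps
# are accepted, so the objective sequence is monotone by construction.
lm_least_squares <- function(fn, x0, jac = NULL, maxit = 100L,
                             ftol = 1e-8, xtol = 1e-10, fd_step = 1e-6,
                             mu0 = 1e-3, max_fev = Inf) {
  x <- as.numeric(x0)
  r <- fn(x)
  fev <- 1L
  obj <- 0.5 * sum(r^2)
  mu <- mu0
  converged <- FALSE
  msg <- "iteration limit reached"
  grad_norm <- NA_real_
  it <- 0L
  if (length(x) == 0L) {
    return(list(par = x, objective = obj, iterations = 0L,
                converged = TRUE, message = "no free parameters",
                grad_norm = 0, fev = fev))
  }
  num_jac <- function(x, r) {
    J <- matrix(0, length(r), length(x))
    for (j in seq_along(x)) {
      h <- fd_step * max(abs(x[j]), 1)
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (fn(xp) - r) / h
    }
    fev <<- fev + length(x)
    J
  }
  while (it < maxit && fev < max_fev) {
    it <- it + 1L
    J <- if (is.null(jac)) num_jac(x, r) else jac(x)
    g <- drop(crossprod(J, r))
    grad_norm <- max(abs(g))
    A <- crossprod(J)
    d <- pmax(diag(A), 1e-12)
    accepted <- FALSE
    for (try in 1:30) {
      step <- tryCatch(
        solve(A + mu * diag(d, length(d)), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        xn <- x + step
        rn <- fn(xn)
        fev <- fev + 1L
        objn <- 0.5 * sum(rn^2)
        if (is.finite(objn) && objn < obj) {
          rel <- (obj - objn) / max(obj, .Machine$double.eps)
          step_size <- max(abs(step) / pmax(abs(x), 1))
          x <- xn; r <- rn; obj <- objn
          mu <- max(mu / 3, 1e-12)
          accepted <- TRUE
          if (rel < ftol) {
            converged <- TRUE; msg <- "relative objective change below ftol"
          } else if (step_size < xtol) {
            converged <- TRUE; msg <- "step size below xtol"
          }
          break
        }
      }
      mu <- mu * 4
    }
    if (!accepted) {
      converged <- TRUE
      msg <- "no decreasing step found (local minimum at tolerance)"
      break
    }
    if (converged) break
  }
  if (!converged && fev >= max_fev) msg <- "function evaluation cap reached"
  list(par = x, objective = obj, iterations = it, converged = converged,
       message = msg, grad_norm = grad_norm, fev = fev)
}
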