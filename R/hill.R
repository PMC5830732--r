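#' Hill regulation functions
#'
#' Sigmoidal saturation functions of a regulator concentration `x` with
#' threshold `Q` and cooperativity exponent `R`.  The inhibiting form is
#' `h^- = Q^R / (x^R + Q^R)`, which decreases from 1 at `x = 0` towards 0;
#' the activating form is `h^+ = 1 + x^R / (x^R + Q^R)`, which increases
#' from 1 at `x = 0` towards 2.  Both are half-way through their transition
#' at `x = Q`, and they satisfy the complementarity identity
#' `h^-(x,Q,R) + (h^+(x,Q,R) - 1) = 1`.
#'
#' Evaluation uses the ratio form `t = (x/Q)^R`, computed as
#' `exp(R * (log(x) - log(Q)))` with an explicit branch at `x = 0`, so that
#' extreme thresholds (e.g. `Q ~ 1e6`) and large exponents do not overflow:
#' `t = Inf` maps to the saturation limits 0 and 2 exactly.
#'
#' @param x regulator concentration, non-negative (vectorized).
#' @param Q threshold parameter, strictly positive.
#' @param R cooperativity exponent, strictly positive.
#' @return `hill_inhibitor`: values in `(0, 1]`; `hill_activator`: values in
#'   `[1, 2)` (the limits 0 and 2 are attainable only in floating point).
#' @examples
#' hill_inhibitor(2, Q = 2, R = 3)   # half-saturation: 0.5
#' hill_activator(5, Q = 5, R = 2)   # half-saturation: 1.5
#' @export
hill_inhibitor <- function(x, Q, R) {
  check_hill_args(x, Q, R)
  1 / (1 + hill_ratio(x, Q, R))
}

#' @rdname hill_inhibitor
#' @export
hill_activator <- function(x, Q, R) {
  check_hill_args(x, Q, R)
  u <- hill_saturation(x, Q, R)
  1 + u
}

check_hill_args <- function(x, Q, R) {
  if (any(!is.finite(Q)) || any(Q <= 0))
    stop("Hill threshold Q must be strictly positive", call. = FALSE)
  if (any(!is.finite(R)) || any(R <= 0))
    stop("Hill exponent R must be strictly positive", call. = FALSE)
  if (any(is.na(x)) || any(x < 0))
    stop("regulator concentration x must be non-negative", call. = FALSE)
  invisible(TRUE)
}

# (x/Q)^R via logs; x = 0 -> 0, huge x -> Inf (handled by callers).
hill_ratio <- function(x, Q, R) {
  t <- numeric(length(x))
  pos <- x > 0
  t[pos] <- exp(R * (log(x[pos]) - log(Q)))
  t
}

# u = t/(1+t) in [0, 1); stable at t = Inf.
hill_saturation <- function(x, Q, R) {
  t <- hill_ratio(x, Q, R)
  u <- t / (1 + t)
  u[is.infinite(t)] <- 1
  u
}

# Internal fast paths used by the ODE right-hand side and its Jacobian.
# `x` may come from a spline curve and dip slightly below zero; it is
# clamped at 0 (the Hill functions are extended as constants there).
hill_eval <- function(x, Q, R, activating) {
  x <- pmax(x, 0)
  u <- hill_saturation(x, Q, R)
  if (activating) 1 + u else 1 - u
}

# d h^+/dx = R/x * u * (1 - u);  d h^-/dx is its negative.  At x <= 0 the
# clamped extension has derivative 0 for R > 1; for R <= 1 the one-sided
# derivative at 0 is unbounded and is returned as 0 (the quadrature nodes
# of the estimator never sit exactly on a boundary state in practice).
hill_deriv <- function(x, Q, R, activating) {
  d <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) {
    u <- hill_saturation(x[pos], Q, R)
    d[pos] <- R / x[pos] * u * (1 - u)
  }
  if (activating) d else -d
}
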