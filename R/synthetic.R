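#' Specification of a synthetic benchmark world
#'
#' Describes how to generate a random signed network, ground-truth kinetic
#' parameters, and a noisy sparse time-series dataset with the structure
#' the estimator assumes.  Defaults emulate the sparse-microarray regime:
#' few sample times relative to the `2(M+N)` unknowns, strictly positive
#' heteroscedastic observations (multiplicative log-normal noise), and
#' parameter ranges spanning the published SOS-response estimates
#' (P in [0.2, 35], S in [0.02, 1.2], Q in [0.5, 400], R in [0.6, 5];
#' the one extreme synthesis/degradation pair of that model is left out of
#' the default ranges as non-representative).
#'
#' @param n_genes,n_edges network size; `n_edges <= n_genes^2` (duplicate
#'   (regulator, target) pairs are forbidden, self-loops are allowed).
#' @param activator_frac probability that an edge is activating.
#' @param P_range,S_range,Q_range,R_range log-uniform sampling bounds for
#'   the ground-truth parameters (all strictly positive).
#' @param x0_range log-uniform bounds for the initial state.
#' @param n_times number of observation times (default 8, the sparse
#'   regime; use 25+ for recovery benchmarks).
#' @param t_span observation window in seconds.
#' @param noise `"lognormal"` (multiplicative, default) or `"additive"`
#'   (Gaussian truncated at zero).
#' @param sigma noise scale (log-sd for `"lognormal"`, sd in mM for
#'   `"additive"`).
#' @param seed mandatory integer seed; all generators are deterministic
#'   functions of it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 3L, n_edges = 4L, activator_frac = 0.5,
                           P_range = c(0.2, 35), S_range = c(0.02, 1.2),
                           Q_range = c(0.5, 400), R_range = c(0.6, 5),
                           x0_range = c(0.5, 20),
                           n_times = 8L, t_span = c(0, 20),
                           noise = c("lognormal", "additive"), sigma = 0.1,
                           seed) {
  if (missing(seed) || !is.finite(seed))
    stop("an explicit integer seed is required", call. = FALSE)
  noise <- match.arg(noise)
  n_genes <- as.integer(n_genes); n_edges <- as.integer(n_edges)
  stopifnot(n_genes >= 1L, n_edges >= 0L, n_edges <= n_genes^2,
            activator_frac >= 0, activator_frac <= 1,
            all(c(P_range, S_range, Q_range, R_range, x0_range) > 0),
            length(t_span) == 2L, t_span[2] > t_span[1],
            n_times >= 2L, sigma >= 0)
  structure(list(n_genes = n_genes, n_edges = n_edges,
                 activator_frac = activator_frac,
                 P_range = P_range, S_range = S_range,
                 Q_range = Q_range, R_range = R_range,
                 x0_range = x0_range, n_times = as.integer(n_times),
                 t_span = as.numeric(t_span), noise = noise, sigma = sigma,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global RNG state is untouched (no hidden global randomness).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Generate a random signed network
#'
#' Draws `n_edges` distinct (regulator, target) ordered pairs uniformly
#' (self-loops allowed) and assigns each a sign with probability
#' `activator_frac` of activation.  Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed (default `spec$seed`).
#' @return A [grn_network()] with genes `g1 ... gN`.
#' @export
generate_network <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  N <- spec$n_genes; M <- spec$n_edges
  with_seed(seed, {
    pair_id <- sample.int(N * N, M)
    reg <- ((pair_id - 1L) %% N) + 1L
    tgt <- ((pair_id - 1L) %/% N) + 1L
    sgn <- ifelse(stats::runif(M) < spec$activator_frac, 1L, -1L)
    grn_network(paste0("g", seq_len(N)), regulator = reg, target = tgt,
                sign = sgn)
  })
}

#' Draw ground-truth kinetic parameters
#'
#' Log-uniform draws inside the spec's ranges, independent per parameter.
#'
#' @param network a [grn_network()].
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed (default `spec$seed + 1`, so network and truth are
#'   independent draws from the same master seed).
#' @return A [grn_params()].
#' @export
generate_truth <- function(network, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(network, "grn_network"), inherits(spec, "synthetic_spec"))
  with_seed(seed, {
    grn_params(P = runif_log(network$n_genes, spec$P_range),
               S = runif_log(network$n_genes, spec$S_range),
               Q = runif_log(network$n_edges, spec$Q_range),
               R = runif_log(network$n_edges, spec$R_range),
               network = network)
  })
}

#' Designed parameter-recovery benchmark world
#'
#' A fixed 3-gene / 4-edge system used to benchmark end-to-end parameter
#' recovery.  Randomly drawn Hill systems are frequently structurally
#' unidentifiable (a regulator that never crosses its threshold leaves
#' `Q`, `R` of that edge unconstrained by any data), so the benchmark is
#' designed instead: a relay with negative feedback
#' (`gA -> gB -> gC -| gA`, plus `gB -> gA`), thresholds placed at the
#' midpoint of each regulator's trajectory range, steady state
#' `(3, 4, 5)` mM by construction, and an initial state displaced so every
#' regulator sweeps across its threshold.  Identifiability was the design
#' criterion (see the methods vignette).  Sampling follows the sparse
#' benchmark regime: 25 equally spaced observations on `[0, 15]` s.
#'
#' @param sigma multiplicative log-normal noise scale (0 = noise-free).
#' @param seed seed for the observation noise (the system itself is
#'   fixed).
#' @return List with `network`, `truth` (a [grn_params()]), `data`
#'   (a [grn_data()]), and `x0`.
#' @export
recovery_benchmark <- function(sigma = 0, seed = 1L) {
  network <- grn_network(c("gA", "gB", "gC"),
                         regulator = c("gA", "gB", "gC", "gB"),
                         target    = c("gB", "gC", "gA", "gA"),
                         sign      = c("+", "+", "-", "+"))
  S <- c(0.6, 0.4, 0.5)
  x_star <- c(3, 4, 5)
  Q <- c(2, 6, 3.5, 6)
  R <- c(2.2, 1.6, 2.8, 2.0)
  # synthesis rates chosen so x_star is an exact fixed point
  P <- c(S[1] * x_star[1] / (hill_activator(x_star[2], Q[4], R[4]) *
                               hill_inhibitor(x_star[3], Q[3], R[3])),
         S[2] * x_star[2] / hill_activator(x_star[1], Q[1], R[1]),
         S[3] * x_star[3] / hill_activator(x_star[2], Q[2], R[2]))
  truth <- grn_params(P = P, S = S, Q = Q, R = R, network = network)
  x0 <- c(0.5, 8, 2)
  times <- seq(0, 15, length.out = 25L)
  traj <- simulate_grn(network, truth, x0, t_span = c(0, 15), grid = times)
  values <- if (sigma > 0) {
    with_seed(seed, traj$states *
                exp(matrix(stats::rnorm(length(traj$states), sd = sigma),
                           nrow(traj$states))))
  } else traj$states
  data <- grn_data(times, values, t0 = 0, tf = 15)
  attr(data, "trajectory") <- traj$states
  list(network = network, truth = truth, data = data, x0 = x0)
}

#' Generate a noisy sparse dataset from a ground-truth model
#'
#' Simulates the ODE from a random positive initial state, samples the
#' trajectory at `n_times` equally spaced times, and applies the noise
#' model: multiplicative log-normal (`y = x * exp(sigma * z)`) or additive
#' Gaussian truncated at zero.  The noise-free samples are kept in the
#' `"trajectory"` attribute and the initial state in `"x0"`.
#'
#' @param network a [grn_network()].
#' @param truth a [grn_params()] (ground truth).
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed (default `spec$seed + 2`).
#' @return A [grn_data()] with attributes `trajectory` and `x0`.
#' @export
generate_dataset <- function(network, truth, spec, seed = spec$seed + 2L) {
  stopifnot(inherits(network, "grn_network"), inherits(truth, "grn_params"),
            inherits(spec, "synthetic_spec"))
  times <- seq(spec$t_span[1], spec$t_span[2], length.out = spec$n_times)
  with_seed(seed, {
    x0 <- runif_log(network$n_genes, spec$x0_range)
    traj <- simulate_grn(network, truth, x0, t_span = spec$t_span,
                         grid = times)
    clean <- traj$states
    noisy <- if (spec$sigma == 0) {
      clean
    } else if (spec$noise == "lognormal") {
      clean * exp(matrix(stats::rnorm(length(clean), sd = spec$sigma),
                         nrow(clean)))
    } else {
      pmax(clean + matrix(stats::rnorm(length(clean), sd = spec$sigma),
                          nrow(clean)), 0)
    }
    out <- grn_data(times, noisy, t0 = spec$t_span[1], tf = spec$t_span[2])
    attr(out, "trajectory") <- clean
    attr(out, "x0") <- x0
    out
  })
}
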