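test_that("Hill functions hit half-saturation, limits and domain errors", {
  expect_equal(hill_inhibitor(0, Q = 2, R = 3), 1)
  expect_equal(hill_inhibitor(2, Q = 2, R = 3), 0.5)
  expect_equal(hill_inhibitor(4, Q = 2, R = 1), 1 / 3)
  expect_equal(hill_activator(0, Q = 5, R = 2), 1)
  for (Q in c(0.3, 2, 40)) for (R in c(0.7, 1, 2.6))
    expect_equal(hill_activator(Q, Q = Q, R = R), 1.5)
  expect_lt(abs(hill_activator(1e6, Q = 1, R = 2) - 2), 1e-11)
  expect_error(hill_inhibitor(1, Q = -1, R = 2), "positive")
  expect_error(hill_activator(1, Q = 1, R = 0), "positive")
  expect_error(hill_inhibitor(-0.1, Q = 1, R = 1), "non-negative")
})

test_that("Hill complementarity and sharpness monotonicity hold", {
  set.seed(42)
  x <- runif(200, 0, 50)
  Q <- runif(200, 0.1, 20)
  R <- runif(200, 0.3, 6)
  expect_equal(hill_inhibitor(x, Q, R) + hill_activator(x, Q, R) - 1,
               rep(1, 200), tolerance = 1e-12)
  # |d h^- / dx| at x = Q grows with the cooperativity exponent
  h <- 1e-6
  slope_at_Q <- vapply(1:3, function(R) {
    abs(hill_inhibitor(2 + h, 2, R) - hill_inhibitor(2 - h, 2, R)) / (2 * h)
  }, numeric(1))
  expect_true(all(diff(slope_at_Q) > 0))
})

test_that("rhs matches the multiplicative Hill model", {
  # isolated gene: pure decay
  iso <- grn_network("g")
  expect_equal(unname(grn_rhs(iso, grn_params(P = 1e-300, S = 1), 3)), -3,
               tolerance = 1e-10)
  # hand-computed 2-gene evaluation
  net <- toy_network()
  par <- toy_params()
  x <- c(1.2, 0.7)
  expected <- c(par$P[1] * hill_activator(x[2], par$Q[2], par$R[2]) -
                  par$S[1] * x[1],
                par$P[2] * hill_activator(x[1], par$Q[1], par$R[1]) -
                  par$S[2] * x[2])
  expect_equal(unname(grn_rhs(net, par, x)), expected)
  # at x = 0 every Hill factor is 1, so production is exactly P
  expect_equal(unname(grn_rhs(net, par, c(0, 0))), par$P)
  # matrix evaluation agrees with row-wise vector evaluation
  X <- rbind(c(0.5, 2), c(3, 0.1), c(0, 0))
  D <- grn_rhs(net, par, X)
  for (r in 1:3) expect_equal(D[r, ], grn_rhs(net, par, X[r, ]))
  expect_error(grn_rhs(net, par, c(1, 2, 3)), "dimension")
})

test_that("non-negative orthant is forward-invariant at the boundary", {
  set.seed(7)
  for (rep in 1:20) {
    spec <- synthetic_spec(n_genes = 4, n_edges = 7, seed = rep)
    net <- generate_network(spec)
    par <- generate_truth(net, spec)
    x <- runif(4, 0, 10)
    i <- sample(4, 1)
    x[i] <- 0
    expect_gte(grn_rhs(net, par, x)[i], 0)
  }
})

test_that("log reparameterization round-trips and always yields positivity", {
  sos <- load_sos()
  back <- from_log(to_log(sos$params), sos$network)
  for (f in c("P", "S", "Q", "R"))
    expect_equal(back[[f]], sos$params[[f]], tolerance = 1e-12)
  th0 <- to_log(grn_params(P = c(1, 1), S = c(1, 1), Q = 1, R = 1,
                           network = NULL))
  expect_true(all(unlist(unclass(th0)) == 0))   # ln 1 = 0 everywhere
  lp <- grn_logparams(p = c(-5, -5), s = c(-5, -5), q = -5, r = -5)
  par <- from_log(lp)
  expect_true(all(unlist(par[c("P", "S", "Q", "R")]) == exp(-5)))
  expect_error(to_log(grn_params(P = 1, S = 1)), NA)
  expect_error(grn_params(P = -1, S = 1), "positive")
})

test_that("from_log is positive for a large sample of real log-parameters", {
  set.seed(11)
  draws <- matrix(rnorm(1e5 * 2, sd = 5), ncol = 2)
  ok <- TRUE
  for (i in seq_len(nrow(draws))) {
    par <- from_log(grn_logparams(p = draws[i, 1], s = draws[i, 2]))
    ok <- ok && par$P > 0 && par$S > 0
    if (!ok) break
  }
  expect_true(ok)
})

test_that("parameter_count follows 2(M+N) / M+2N / M", {
  expect_identical(unname(parameter_count(load_sos()$network)),
                   c(104L, 61L, 43L))
  expect_identical(unname(parameter_count(grn_network("g"))), c(2L, 2L, 0L))
  spec <- synthetic_spec(n_genes = 3, n_edges = 4, seed = 1)
  expect_identical(unname(parameter_count(generate_network(spec))),
                   c(14L, 10L, 4L))
})

test_that("network construction validates its invariants", {
  expect_error(grn_network(c("a", "a")), "unique")
  expect_error(grn_network("a", "a", "b", "+"), "unknown target")
  expect_error(grn_network(c("a", "b"), c("a", "a"), c("b", "b"),
                           c("+", "-")), "duplicate")
  expect_error(grn_network(c("a", "b"), "a", "b", "x"), "sign")
  # self-loops are legal
  expect_silent(grn_network("a", "a", "a", "-"))
})

test_that("rhs state-Jacobian matches finite differences", {
  net <- toy_network()
  par <- toy_params()
  x <- c(1.7, 2.2)
  J <- hillgpm:::rhs_jacobian(net, par, x)
  h <- 1e-7
  for (j in 1:2) {
    xp <- x; xp[j] <- xp[j] + h
    fd <- unname(grn_rhs(net, par, xp) - grn_rhs(net, par, x)) / h
    expect_equal(J[, j], fd, tolerance = 1e-5)
  }
})
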