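test_that("generate_network draws the requested structure deterministically", {
  spec <- synthetic_spec(n_genes = 3, n_edges = 4, seed = 1)
  net <- generate_network(spec)
  expect_equal(net$n_genes, 3L)
  expect_equal(net$n_edges, 4L)
  net2 <- generate_network(spec)
  expect_identical(as.data.frame(net), as.data.frame(net2))
  # saturation: complete graph including self-loops
  full <- synthetic_spec(n_genes = 3, n_edges = 9, seed = 2)
  netf <- generate_network(full)
  expect_equal(netf$n_edges, 9L)
  expect_equal(nrow(unique(as.data.frame(netf)[, 1:2])), 9L)
  expect_error(synthetic_spec(n_genes = 3, n_edges = 10, seed = 1))
  expect_error(synthetic_spec(n_genes = 3, n_edges = 4), "seed")
})

test_that("generate_truth respects its log-uniform bounds and seed", {
  spec <- synthetic_spec(n_genes = 4, n_edges = 10, seed = 5)
  net <- generate_network(spec)
  tru <- generate_truth(net, spec)
  expect_true(all(tru$P >= 0.2 & tru$P <= 35))
  expect_true(all(tru$S >= 0.02 & tru$S <= 1.2))
  expect_true(all(tru$Q >= 0.5 & tru$Q <= 400))
  expect_true(all(tru$R >= 0.6 & tru$R <= 5))
  tru2 <- generate_truth(net, spec)
  expect_identical(tru$Q, tru2$Q)
})

test_that("ln R draws are uniform on their range (KS check on 1e4 draws)", {
  spec <- synthetic_spec(n_genes = 10, n_edges = 100, seed = 8)
  net <- generate_network(spec)
  draws <- unlist(lapply(1:100, function(s) {
    generate_truth(net, spec, seed = 1000L + s)$R
  }))
  expect_length(draws, 1e4)
  u <- (log(draws) - log(0.6)) / (log(5) - log(0.6))
  expect_true(all(u >= 0 & u <= 1))
  ks <- max(abs(sort(u) - (seq_along(u) - 0.5) / length(u)))
  expect_lt(ks, 0.05)
})

test_that("sigma = 0 datasets equal the noise-free trajectory samples", {
  spec <- synthetic_spec(n_genes = 3, n_edges = 4,
                         P_range = c(1, 10), S_range = c(0.1, 1),
                         Q_range = c(1, 10), R_range = c(1, 3),
                         x0_range = c(0.5, 5), sigma = 0, seed = 3)
  net <- generate_network(spec)
  tru <- generate_truth(net, spec)
  dat <- generate_dataset(net, tru, spec)
  expect_identical(dat$values, attr(dat, "trajectory"))
  expect_equal(length(dat$times), spec$n_times)
  # determinism
  dat2 <- generate_dataset(net, tru, spec)
  expect_identical(dat$values, dat2$values)
})

test_that("additive noise is clamped at zero and values stay non-negative", {
  spec <- synthetic_spec(n_genes = 2, n_edges = 2,
                         P_range = c(0.5, 1), S_range = c(0.5, 1),
                         Q_range = c(1, 5), R_range = c(1, 2),
                         x0_range = c(0.5, 1), noise = "additive",
                         sigma = 5, seed = 6)
  net <- generate_network(spec)
  tru <- generate_truth(net, spec)
  dat <- generate_dataset(net, tru, spec)
  expect_true(all(dat$values >= 0))
})

test_that("log-normal noise has mean true * exp(sigma^2/2)", {
  # one long trajectory gives 1e4 iid multiplicative noise draws
  spec <- synthetic_spec(n_genes = 2, n_edges = 2,
                         P_range = c(2, 4), S_range = c(0.3, 0.6),
                         Q_range = c(2, 5), R_range = c(1, 2),
                         x0_range = c(1, 3), n_times = 5000,
                         t_span = c(0, 10), sigma = 0.1, seed = 10)
  net <- generate_network(spec)
  tru <- generate_truth(net, spec)
  dat <- generate_dataset(net, tru, spec)
  ratio <- dat$values / attr(dat, "trajectory")
  expect_equal(mean(ratio), exp(0.1^2 / 2), tolerance = 0.02)
})

test_that("the designed recovery benchmark is reproducible and identifiable", {
  bm <- recovery_benchmark(sigma = 0)
  expect_equal(bm$network$n_genes, 3L)
  expect_equal(bm$network$n_edges, 4L)
  # the stated steady state is an exact fixed point of the truth
  ss <- steady_state(bm$network, bm$truth, c(3, 4, 5))
  expect_equal(as.numeric(ss), c(3, 4, 5), tolerance = 1e-8)
  # every regulator's sampled trajectory crosses its edge's threshold
  rng <- apply(bm$data$values, 2, range)
  for (k in seq_len(4)) {
    reg <- bm$network$reg[k]
    expect_lt(rng[1, reg], bm$truth$Q[k])
    expect_gt(rng[2, reg], bm$truth$Q[k])
  }
  # noise seeds change only the observations, not the system
  bm2 <- recovery_benchmark(sigma = 0.05, seed = 2)
  expect_identical(bm$truth$Q, bm2$truth$Q)
  expect_false(identical(bm$data$values, bm2$data$values))
})
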