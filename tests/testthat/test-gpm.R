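# Small 2-gene world used throughout: mutual activation, noise-free
# samples dense enough for recovery at modest basis resolution.
gpm_world <- function(sigma = 0, seed = 11L) {
  spec <- synthetic_spec(n_genes = 2, n_edges = 2,
                         P_range = c(1, 5), S_range = c(0.2, 0.8),
                         Q_range = c(1, 8), R_range = c(1, 3),
                         x0_range = c(0.5, 5), n_times = 25,
                         t_span = c(0, 15), sigma = sigma, seed = seed)
  net <- generate_network(spec)
  list(spec = spec, network = net,
       truth = generate_truth(net, spec),
       data = generate_dataset(net, generate_truth(net, spec), spec))
}

test_that("inner objective reduces to plain least squares as lambda -> 0", {
  w <- gpm_world()
  cfg <- gpm_config(lambda = 1e-300, knots = 15)
  basis <- spline_basis(w$data$t0, w$data$tf, knots = 15)
  C <- smoothing_fit(basis, w$data)
  obj <- inner_objective(C, to_log(w$truth), w$data, w$network, basis, cfg)
  sse <- sum((w$data$values - eval_basis(basis, w$data$times) %*% C)^2)
  expect_equal(as.numeric(obj), sse, tolerance = 1e-10)
  # and inner_solve then equals the analytic normal-equations smoother
  sol <- inner_solve(to_log(w$truth), w$data, w$network, basis, cfg,
                     coefs_init = C + 0.05)
  Phi <- eval_basis(basis, w$data$times)
  C_ls <- solve(crossprod(Phi), crossprod(Phi, w$data$values))
  expect_equal(unname(sol$coefs), unname(C_ls), tolerance = 1e-6)
})

test_that("doubling lambda doubles the penalty term and keeps the data term", {
  w <- gpm_world()
  basis <- spline_basis(w$data$t0, w$data$tf, knots = 20)
  C <- smoothing_fit(basis, w$data)
  th <- to_log(w$truth)
  o1 <- inner_objective(C, th, w$data, w$network, basis,
                        gpm_config(lambda = 150, knots = 20))
  o2 <- inner_objective(C, th, w$data, w$network, basis,
                        gpm_config(lambda = 300, knots = 20))
  expect_equal(attr(o2, "data_term"), attr(o1, "data_term"))
  expect_equal(attr(o2, "penalty_term"), 2 * attr(o1, "penalty_term"),
               tolerance = 1e-12)
})

test_that("inner objective is near zero on an exact noise-free trajectory", {
  w <- gpm_world()
  basis <- spline_basis(0, 15, knots = 60)
  dense <- seq(0, 15, length.out = 400)
  traj <- simulate_grn(w$network, w$truth, attr(w$data, "x0"),
                       c(0, 15), grid = dense)
  dat_dense <- grn_data(dense, traj$states)
  C <- smoothing_fit(basis, dat_dense)
  obj <- inner_objective(C, to_log(w$truth), dat_dense, w$network, basis,
                         gpm_config(knots = 60))
  expect_lt(as.numeric(obj), 1e-4 * max(w$data$values)^2)
})

test_that("inner_solve descends from its initializer and tracks the ODE", {
  w <- gpm_world()
  cfg <- gpm_config(knots = 30)
  basis <- spline_basis(w$data$t0, w$data$tf, knots = 30)
  th <- to_log(w$truth)
  C0 <- smoothing_fit(basis, w$data, ridge = cfg$ridge)
  obj0 <- inner_objective(C0, th, w$data, w$network, basis, cfg)
  sol <- inner_solve(th, w$data, w$network, basis, cfg)
  expect_lte(sol$objective, as.numeric(obj0))
  # reconstructed curve near the true trajectory (noise-free data)
  dense <- seq(0, 15, length.out = 120)
  traj <- simulate_grn(w$network, w$truth, attr(w$data, "x0"),
                       c(0, 15), grid = dense)
  fit_curve <- eval_basis(basis, dense) %*% sol$coefs
  rng <- diff(range(traj$states))
  expect_lt(max(abs(fit_curve - traj$states)), 0.01 * rng)
  # penalty dominance at very large lambda on noise-free data
  cfg_big <- gpm_config(lambda = 1e6, knots = 30)
  sol_big <- inner_solve(th, w$data, w$network, basis, cfg_big)
  expect_lt(sol_big$penalty_term / 1e6, sol_big$data_term + 1e-6)
})

test_that("penalty term at the inner solution is non-increasing in lambda", {
  w <- gpm_world()
  basis <- spline_basis(w$data$t0, w$data$tf, knots = 30)
  th <- to_log(w$truth)
  pens <- vapply(c(1, 150, 1e4), function(lam) {
    cfg <- gpm_config(lambda = lam, knots = 30)
    sol <- inner_solve(th, w$data, w$network, basis, cfg)
    sol$penalty_term / lam   # integral of squared ODE mismatch
  }, numeric(1))
  expect_true(all(diff(pens) <= 1e-10))
})

test_that("outer objective: non-negative, small at truth, larger off truth", {
  w <- gpm_world()
  cfg <- gpm_config(knots = 40)
  th <- to_log(w$truth)
  o_true <- outer_objective(th, w$data, w$network, config = cfg)
  expect_gte(as.numeric(o_true), 0)
  expect_lt(as.numeric(o_true), 1e-3 * max(w$data$values)^2)
  th_r <- th
  th_r$r[1] <- th_r$r[1] + 1
  o_pert <- outer_objective(th_r, w$data, w$network, config = cfg)
  expect_gt(as.numeric(o_pert), as.numeric(o_true))
})

test_that("profiled objective is first-order stationary at the truth", {
  w <- gpm_world()
  cfg <- gpm_config(knots = 40)
  ws <- hillgpm:::gpm_workspace(w$network, w$data, cfg)
  grad_at <- function(lp, params) {
    sol <- hillgpm:::inner_solve_ws(lp, ws, cfg)
    J <- hillgpm:::profiled_jacobian(sol$coefs, params, ws, rep(TRUE, 8))
    r <- hillgpm:::profiled_residuals(lp, ws, cfg, sol$coefs)$residuals
    max(abs(drop(crossprod(J, r))))
  }
  th <- to_log(w$truth)
  g_true <- grad_at(th, w$truth)
  th_p <- th
  th_p$q <- th_p$q + 0.1
  g_pert <- grad_at(th_p, from_log(th_p))
  # gradient at truth is far below the gradient a short distance away
  expect_lt(g_true, 0.05 * g_pert)
})

test_that("outer_solve honours an empty free set and descends otherwise", {
  w <- gpm_world()
  cfg <- gpm_config(knots = 50)
  th <- to_log(w$truth)
  res <- outer_solve(th, rep(FALSE, 8), w$data, w$network, config = cfg)
  expect_identical(res$theta, th)
  expect_equal(res$iterations, 0L)
  # perturb theta_p by ~20%, keep r at truth, recover P, S, Q
  th_p <- th
  set.seed(2)
  th_p$p <- th_p$p + runif(2, -0.2, 0.2)
  th_p$s <- th_p$s + runif(2, -0.2, 0.2)
  th_p$q <- th_p$q + runif(2, -0.2, 0.2)
  fit <- outer_solve(th_p, "theta_p", w$data, w$network, config = cfg)
  expect_lte(fit$objective, fit$objective_init)
  est <- from_log(fit$theta)
  for (f in c("P", "S", "Q"))
    expect_lt(max(abs(est[[f]] - w$truth[[f]]) / w$truth[[f]]), 0.05)
})

test_that("fd and cascade outer gradients agree on accepted descent", {
  w <- gpm_world()
  th0 <- initial_theta(w$network, w$data)
  fit_c <- outer_solve(th0, "theta_p", w$data, w$network,
                       config = gpm_config(knots = 30, outer_maxit = 30))
  fit_f <- outer_solve(th0, "theta_p", w$data, w$network,
                       config = gpm_config(knots = 30, outer_maxit = 30,
                                           gradient = "fd"))
  expect_lt(fit_c$objective, fit_c$objective_init)
  expect_lt(fit_f$objective, fit_f$objective_init)
})
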