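test_that("basis dimension and domain checks follow the clamped convention", {
  b <- spline_basis(0, 10, order = 4, knots = 100)
  expect_equal(b$dim, 102)
  expect_error(eval_basis(b, 10.5), "outside")
  expect_error(spline_basis(1, 1), "t0 < tf")
})

test_that("partition of unity and derivative row sums hold at random points", {
  b <- spline_basis(-2, 7, order = 4, knots = 37)
  set.seed(5)
  t <- c(-2, 7, runif(1e4, -2, 7))
  expect_lt(max(abs(rowSums(eval_basis(b, t)) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(eval_basis_deriv(b, t)))), 1e-9)
})

test_that("order-2 basis is the linear hat system", {
  b <- spline_basis(0, 4, order = 2, knots = 5)
  Phi <- eval_basis(b, 0:4)
  expect_equal(Phi, diag(5))
})

test_that("constant coefficients reproduce 1 and derivative 0", {
  b <- spline_basis(0, 1, order = 4, knots = 12)
  t <- seq(0, 1, length.out = 57)
  expect_equal(drop(eval_basis(b, t) %*% rep(1, b$dim)), rep(1, 57))
  expect_lt(max(abs(eval_basis_deriv(b, t) %*% rep(1, b$dim))), 1e-10)
})

test_that("a dense fit of t^2 has derivative close to 2t", {
  b <- spline_basis(0, 1, order = 4, knots = 100)
  tt <- seq(0, 1, length.out = 500)
  dat <- grn_data(tt, matrix(tt^2, ncol = 1, dimnames = list(NULL, "g")))
  C <- smoothing_fit(b, dat, ridge = 1e-10)
  interior <- seq(0.05, 0.95, length.out = 200)
  dfit <- drop(eval_basis_deriv(b, interior) %*% C)
  expect_lt(max(abs(dfit - 2 * interior)), 1e-3)
})

test_that("quadrature weights measure the domain and integrate exactly", {
  b <- spline_basis(0, 10, knots = 23)
  q <- quadrature_grid(b, 4)
  expect_equal(sum(q$weights), 10, tolerance = 1e-12)
  # exact for polynomials up to degree 2*points - 1 on random intervals
  set.seed(9)
  for (rep in 1:5) {
    a <- runif(1, -3, 0); z <- runif(1, 1, 4)
    bb <- spline_basis(a, z, knots = 7)
    qq <- quadrature_grid(bb, 3)   # exact through degree 5
    for (d in 0:5) {
      expect_equal(sum(qq$weights * qq$times^d),
                   (z^(d + 1) - a^(d + 1)) / (d + 1), tolerance = 1e-10)
    }
  }
  qs <- quadrature_grid(spline_basis(0, 2 * pi, knots = 50), 5)
  expect_equal(sum(qs$weights * sin(qs$times)^2), pi, tolerance = 1e-6)
})

test_that("smoothing_fit interpolates exact spline data and fits constants", {
  b <- spline_basis(0, 5, order = 4, knots = 9)
  set.seed(3)
  c_true <- rnorm(b$dim)
  tt <- seq(0, 5, length.out = 40)
  y <- drop(eval_basis(b, tt) %*% c_true)
  dat <- grn_data(tt, matrix(pmax(y + 10, 0), ncol = 1,
                             dimnames = list(NULL, "g")))
  C <- smoothing_fit(b, dat, ridge = 0)
  fit <- drop(eval_basis(b, tt) %*% C)
  expect_lt(max(abs(fit - (pmax(y + 10, 0)))), 1e-9)
  # constant data reproduce the constant
  dat5 <- grn_data(tt, matrix(5, length(tt), 1, dimnames = list(NULL, "g")))
  C5 <- smoothing_fit(b, dat5)
  expect_equal(drop(eval_basis(b, seq(0, 5, 0.1)) %*% C5),
               rep(5, 51), tolerance = 1e-6)
})

test_that("ridge makes the rank-deficient fit unique and stationary", {
  b <- spline_basis(0, 1, order = 4, knots = 30)   # 32 basis fns, 6 samples
  tt <- seq(0, 1, length.out = 6)
  y <- sin(tt) + 1
  dat <- grn_data(tt, matrix(y, ncol = 1, dimnames = list(NULL, "g")))
  C <- smoothing_fit(b, dat, ridge = 1e-6)
  X <- eval_basis(b, tt)
  # projected-gradient optimality of the ridge objective
  grad <- -2 * crossprod(X, y - X %*% C) + 2 * 1e-6 * C
  expect_lt(max(abs(grad)), 1e-8)
  # any random perturbation increases the ridge objective
  obj <- function(cc) sum((y - X %*% cc)^2) + 1e-6 * sum(cc^2)
  set.seed(8)
  for (rep in 1:10)
    expect_gt(obj(C + rnorm(length(C), sd = 0.01)), obj(C))
})
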