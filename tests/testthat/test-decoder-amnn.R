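# Additive monotonic decoder: positive integrands, signed quadrature,
# monotone scores, complementary log-log likelihood.

zero_integrand <- function() {
  # 1 -> 1 "network" with all-zero weights: h(s) = exp(0) = 1
  list(list(W = matrix(0, 1, 4), b = matrix(0, 1, 4)),
       list(W = matrix(0, 4, 1), b = matrix(0, 1, 1)))
}

linear_integrand <- function() {
  # net(s) = s via a wide-linear trick is not exact with tanh hidden; use a
  # direct 1 -> 1 layer pair: W2 * tanh(W1 s) ~ s only approximately, so for
  # exact closed forms we use a degenerate single linear layer
  list(list(W = matrix(1, 1, 1), b = matrix(0, 1, 1)))
}

test_that("integrands are strictly positive and exact for degenerate weights", {
  th <- zero_integrand()
  expect_equal(amnn_integrand(c(-3, 0, 11), th), c(1, 1, 1))
  expect_equal(amnn_integrand(1, linear_integrand()), exp(1))
  am <- amnn_params(3, seed = 5)
  s <- rnorm(50)
  for (j in 1:3) expect_true(all(amnn_integrand(s, am$integrands[[j]]) > 0))
})

test_that("trapezoidal integration is signed, exact for constants, and accurate", {
  th <- zero_integrand()
  expect_equal(integrate_dim(0, th, l = -10, n_grid = 64), 10)
  expect_equal(integrate_dim(-10, th, l = -10, n_grid = 64), 0)
  expect_equal(integrate_dim(-12, th, l = -10, n_grid = 16), -2)  # signed
  # int_0^1 e^s ds = e - 1 within 1e-4 at n_grid = 512
  I <- integrate_dim(1, linear_integrand(), l = 0, n_grid = 512)
  expect_equal(I, exp(1) - 1, tolerance = 1e-4 / (exp(1) - 1))
  expect_lt(abs(I - (exp(1) - 1)), 1e-4)
})

test_that("quadrature error at least halves when the grid doubles", {
  set.seed(9)
  for (r in 1:5) {
    am <- amnn_params(1, hidden = 8, seed = 100 + r)
    th <- am$integrands[[1]]
    zj <- runif(1, 0.5, 3)
    ref <- integrate_dim(zj, th, l = -2, n_grid = 100000)
    e64 <- abs(integrate_dim(zj, th, l = -2, n_grid = 64) - ref)
    e128 <- abs(integrate_dim(zj, th, l = -2, n_grid = 128) - ref)
    expect_lt(e128, e64 / 2 + 1e-12)
  }
})

test_that("the AMNN score is additive, monotone, and exact in degenerate cases", {
  # constant integrands, alpha = 1, gamma = 0, l = -10, z = 0: H = 2 * 10
  am <- amnn_params(2, lower_end = -10, n_grid = 32, seed = 1)
  am$integrands <- list(zero_integrand(), zero_integrand())
  am$alpha <- matrix(1, 1, 2); am$gamma <- matrix(0, 1, 1)
  expect_equal(amnn_forward(c(0, 0), am), 20)
  # alpha = 0 => H = gamma
  am$alpha <- matrix(0, 1, 2); am$gamma <- matrix(1.3, 1, 1)
  expect_equal(amnn_forward(matrix(rnorm(10), 5), am), rep(1.3, 5))
})

test_that("monotonicity holds across random configurations", {
  set.seed(33)
  for (r in 1:1000) {
    p <- sample(1:3, 1)
    am <- amnn_params(p, hidden = 4, n_grid = 64, seed = 2000 + r)
    am$alpha <- matrix(abs(am$alpha), 1, p)       # force positive direction
    z <- rnorm(p)
    dz <- runif(p, 0, 2) * rbinom(p, 1, 0.6)
    expect_gte(amnn_forward(z + dz, am) - amnn_forward(z, am), -1e-9)
  }
})

test_that("the score gradient equals alpha_j h_j(z_j) within quadrature tolerance", {
  set.seed(14)
  p <- 5
  am <- amnn_params(p, seed = 6)
  z <- matrix(rnorm(4 * p), 4)
  tp <- vie:::ad_tape()
  zn <- vie:::ad_leaf(z, tp)
  w <- vie:::wrap_params(am[c("integrands", "alpha", "gamma")], tp)
  vie:::ad_backward(vie:::ad_sum(amnn_forward(zn, am, w)))
  ref <- sapply(seq_len(p), function(j)
    am$alpha[1, j] * amnn_integrand(z[, j], am$integrands[[j]]))
  expect_lt(max(abs(vie:::ad_grad(zn) - ref)), 1e-3)
})

test_that("complementary log-log likelihood matches closed forms and limits", {
  expect_equal(cll_log_lik(1, 0), log(1 - exp(-1)))
  expect_equal(cll_log_lik(0, 0), -1)
  expect_lt(abs(cll_log_lik(0, -30)), 1e-12)
  expect_error(cll_log_lik(2, 0), "binary")
  # stability at extreme scores
  expect_true(is.finite(cll_log_lik(1, -500)))
  expect_true(is.finite(cll_log_lik(0, 500)))
})

test_that("predicted risk is the inverse link, with the right limits", {
  am <- amnn_params(2, seed = 3)
  am$alpha <- matrix(0, 1, 2)
  am$gamma <- matrix(0, 1, 1)
  expect_equal(predicted_risk(c(0, 0), am), 1 - exp(-1))
  am$gamma <- matrix(-40, 1, 1)
  expect_lt(predicted_risk(c(0, 0), am), 1e-15)
  am$gamma <- matrix(40, 1, 1)
  expect_equal(predicted_risk(c(0, 0), am), 1)
  # monotone in the score through any latent direction with alpha > 0
  # (small weight and negative bias keep the link away from saturation)
  am2 <- amnn_params(1, seed = 4)
  am2$alpha <- matrix(0.15, 1, 1)
  am2$gamma <- matrix(-4, 1, 1)
  zg <- seq(-3, 3, length.out = 30)
  expect_true(all(diff(predicted_risk(matrix(zg, ncol = 1), am2)) > 0))
})
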