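# Generalized Pareto tail and the Gaussian/GPD mixture prior.

test_that("GPD distribution function matches closed forms and clamps at the support", {
  expect_equal(gpd_cdf(0, xi = 0.3, sigma = 1, u = 0), 0)     # zero at threshold
  expect_equal(gpd_cdf(1, xi = 0, sigma = 1, u = 0), 1 - exp(-1))
  expect_equal(gpd_cdf(1, xi = 1, sigma = 1, u = 0), 0.5)
  # below threshold and beyond the bounded upper endpoint (xi < 0)
  expect_equal(gpd_cdf(-1, xi = 0.5, sigma = 1, u = 0), 0)
  expect_equal(gpd_cdf(3, xi = -0.5, sigma = 1, u = 0), 1)    # endpoint at 2
  # non-decreasing on a grid, for several shapes
  xg <- seq(0, 6, length.out = 200)
  for (xi in c(-0.4, -1e-7, 0, 1e-7, 0.2, 1)) {
    p <- gpd_cdf(xg, xi, sigma = 1.3, u = 0)
    expect_true(all(diff(p) >= 0))
  }
  expect_error(gpd_cdf(1, xi = 0, sigma = -1), "positive")
})

test_that("GPD cdf is continuous across the xi -> 0 branch switch", {
  xg <- seq(0.1, 5, length.out = 50)
  for (s in c(0.5, 1, 2)) {
    d <- abs(gpd_cdf(xg, 1e-6, s, 0) - gpd_cdf(xg, 0, s, 0))
    expect_lt(max(d), 1e-6)
    d <- abs(gpd_cdf(xg, -1e-6, s, 0) - gpd_cdf(xg, 0, s, 0))
    expect_lt(max(d), 1e-6)
  }
})

test_that("GPD log-density matches closed forms and finite differences of the cdf", {
  expect_equal(gpd_log_pdf(0, xi = 0, sigma = 1, u = 0), 0)     # Exp(1) at 0
  expect_equal(gpd_log_pdf(2, xi = 0, sigma = 2, u = 0), log(0.5) - 1)
  expect_identical(gpd_log_pdf(-0.5, xi = 0.2, sigma = 1, u = 0), -Inf)
  h <- 1e-5
  for (xi in c(-0.3, 0, 0.5, 1)) {
    for (x in c(0.3, 1, 1.7)) {
      fd <- (gpd_cdf(x + h, xi, 1, 0) - gpd_cdf(x - h, xi, 1, 0)) / (2 * h)
      expect_equal(exp(gpd_log_pdf(x, xi, 1, 0)), fd, tolerance = 1e-4)
    }
  }
})

test_that("tail-parameter translation reproduces the stated formulas", {
  u <- qnorm(0.99)
  tr <- translate_tail_params(0, 1, u)
  expect_equal(tr$sigma_t, 1)
  expect_equal(tr$u_t, u + log(0.01))
  tr <- translate_tail_params(0.5, 1, u)
  expect_equal(tr$xi_t, 0.5)
  expect_equal(tr$sigma_t, sqrt(0.01), tolerance = 1e-12)
})

test_that("mixture cdf is the Gaussian body spliced continuously with the GPD tail", {
  u <- qnorm(0.99)
  pr <- mixed_gpd_prior(3, u = u, xi = c(0.4, 0, -0.2), sigma = c(1, 2, 0.7))
  expect_equal(mixture_cdf(u, pr, 1), pnorm(u))
  expect_equal(mixture_cdf(0, pr, 2), 0.5)
  # continuity at u from both sides, across a (xi, sigma) grid
  for (xi in c(-0.3, 0, 1e-7, 0.2, 0.8)) {
    for (s in c(0.5, 1, 2)) {
      pg <- mixed_gpd_prior(1, u = u, xi = xi, sigma = s)
      left <- mixture_cdf(u - 1e-9, pg, 1)
      right <- mixture_cdf(u + 1e-9, pg, 1)
      expect_lt(abs(right - left), 1e-8)
      expect_lt(abs(right - pnorm(u)), 1e-8)
    }
  }
  # limits
  expect_lt(mixture_cdf(-9, pr, 1), 1e-15)
  expect_gt(mixture_cdf(60, pr, 1), 1 - 1e-3)
})

test_that("mixture log-density agrees with the cdf and integrates to one", {
  u <- qnorm(0.99)
  expect_equal(mixture_log_pdf(0, mixed_gpd_prior(1, u = u), 1),
               -0.5 * log(2 * pi))
  set.seed(31)
  for (r in 1:50) {
    xi <- runif(1, -0.3, 1); s <- runif(1, 0.4, 2.5)
    pr <- mixed_gpd_prior(1, u = u, xi = xi, sigma = s)
    # density vs central difference of the cdf at interior points
    for (z in c(-1.2, 0.4, u + 0.5, u + 1.6)) {
      h <- 1e-5
      fd <- (mixture_cdf(z + h, pr, 1) - mixture_cdf(z - h, pr, 1)) / (2 * h)
      expect_equal(exp(mixture_log_pdf(z, pr, 1)), fd, tolerance = 1e-4)
    }
  }
  # quadrature: total mass 1 within 1e-3
  pr <- mixed_gpd_prior(2, u = u, xi = c(0.5, 0), sigma = c(1, 2))
  for (j in 1:2) {
    upper <- mixture_quantile(1 - 1e-9, pr, j)
    I <- integrate(function(z) exp(mixture_log_pdf(z, pr, j)), -12, upper)
    expect_equal(I$value, 1, tolerance = 1e-3)
  }
})

test_that("inverse-cdf sampling follows the mixture law", {
  u <- qnorm(0.99)
  pr <- mixed_gpd_prior(2, u = u, xi = c(0.3, 0), sigma = c(1, 2))
  z <- mixture_sample(200000, pr, seed = 7)
  expect_identical(dim(z), c(200000L, 2L))
  # exceedance fraction ~ 1 - Phi(u) = 0.01 within 3 binomial s.e.
  se <- sqrt(0.01 * 0.99 / 200000)
  for (j in 1:2) expect_lt(abs(mean(z[, j] > u) - 0.01), 3 * se)
  # seeding contract
  expect_identical(mixture_sample(1, pr, seed = 99), mixture_sample(1, pr, seed = 99))
  # one-sample KS below the 1% critical value at n = 1e5
  zz <- mixture_sample(100000, pr, seed = 1)[, 1]
  Fn <- ecdf(zz)
  grid <- sort(zz)
  D <- max(abs(Fn(grid) - mixture_cdf(grid, pr, 1)))
  expect_lt(D, 1.628 / sqrt(100000))
})

test_that("peaks-over-threshold likelihood recovers the tail shape", {
  u <- qnorm(0.99)
  pr <- mixed_gpd_prior(1, u = u, xi = 0.3, sigma = 1)
  z <- mixture_sample(100000, pr, seed = 5)[, 1]
  fit <- fit_gpd_pot(z, u)
  expect_lt(abs(fit$xi - 0.3), 0.1)
  expect_gt(fit$n_exc, 500)
})
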