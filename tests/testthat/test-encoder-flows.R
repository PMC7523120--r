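# Flow posterior: base encoder, IAF steps, exact log-density, inversion,
# and the density-free implicit sampler.

test_that("encoding is deterministic, positive-scaled, and guards its inputs", {
  enc <- vie_encoder(d = 5, p = 3, flow_depth = 2, seed = 2)
  x <- matrix(rnorm(20), 4)
  a <- encode(x, enc); b <- encode(x, enc)
  expect_identical(a, b)
  expect_true(all(a$sigma0 > 0))
  expect_identical(dim(a$mu0), c(4L, 3L))
  xx <- x; xx[2, 3] <- NaN
  expect_error(encode(xx, enc), "finite")
  expect_error(encode(matrix(0, 2, 7), enc), "dimension")
  # zero output layer => sigma0 is softplus(0) for every input
  enc0 <- enc
  nl <- length(enc0$params$enc)
  enc0$params$enc[[nl]]$W[] <- 0; enc0$params$enc[[nl]]$b[] <- 0
  e0 <- encode(x, enc0)
  expect_equal(unique(as.numeric(e0$sigma0)), log(2), tolerance = 1e-12)
})

test_that("identity and fixed-affine flow steps act as written", {
  enc <- vie_encoder(d = 4, p = 3, flow_depth = 1, seed = 5)
  x <- matrix(rnorm(8), 2)
  eo <- encode(x, enc)
  eps <- matrix(rnorm(6), 2)
  # force mu_t = 0, sigma_t = 1: zero conditioner output layer, bias s.t.
  # sigmoid(b + 1.5) = 1 is impossible exactly; use a large bias
  encI <- enc
  encI$params$flows[[1]]$out$W[] <- 0
  encI$params$flows[[1]]$out$b[] <- c(rep(0, 3), rep(100, 3))  # mu heads, s heads
  path <- flow_forward(eps, eo, encI)
  z0 <- eo$mu0 + eo$sigma0 * eps
  expect_equal(ad_value(path$z), z0, tolerance = 1e-12)
  lq_gauss <- rowSums(dnorm(z0, eo$mu0, eo$sigma0, log = TRUE))
  expect_equal(flow_log_q(path), lq_gauss, tolerance = 1e-10)
})

test_that("T = 0 reduces to the diagonal Gaussian; closed forms hold", {
  enc <- vie_encoder(d = 4, p = 1, flow_depth = 0, seed = 3)
  # p = 1, mu0 = 0, sigma0 = 2, z0 = 2 => -1/2 - log(2pi)/2 - log 2
  eo <- list(mu0 = matrix(0, 1, 1), sigma0 = matrix(2, 1, 1),
             context = matrix(0, 1, enc$context_dim))
  path <- flow_forward(matrix(1, 1, 1), eo, enc)   # z0 = 0 + 2*1 = 2
  expect_equal(flow_log_q(path), -0.5 - 0.5 * log(2 * pi) - log(2))
  # z0 at the mode with unit scale: -(p/2) log(2pi)
  eo2 <- list(mu0 = matrix(0, 1, 1), sigma0 = matrix(1, 1, 1),
              context = matrix(0, 1, enc$context_dim))
  path2 <- flow_forward(matrix(0, 1, 1), eo2, enc)
  expect_equal(flow_log_q(path2), -0.5 * log(2 * pi))
})

test_that("flow log-density equals the change-of-variables Jacobian oracle", {
  skip_if_not_installed("pracma")
  set.seed(12)
  enc <- vie_encoder(d = 3, p = 2, flow_depth = 2, seed = 7)
  x <- matrix(rnorm(3), 1)
  eo <- encode(x, enc)
  eps <- matrix(rnorm(2), 1)
  path <- flow_forward(eps, eo, enc)
  ctx <- ad_value(eo$context)
  fmap <- function(z0v) {
    z <- matrix(z0v, 1)
    for (t in 1:2) {
      cond <- vie:::conditioner_forward(z, ctx, enc$params$flows[[t]], enc$masks)
      sig <- plogis(ad_value(cond$s_raw) + 1.5)
      z <- ad_value(cond$mu) + sig * z
    }
    as.numeric(z)
  }
  z0 <- path$z_steps[[1]][1, ]
  J <- pracma::jacobian(fmap, z0)
  lq_oracle <- sum(dnorm(z0, ad_value(eo$mu0), ad_value(eo$sigma0),
                         log = TRUE)) - log(abs(det(J)))
  expect_equal(flow_log_q(path), lq_oracle, tolerance = 1e-6)
})

test_that("conditioner Jacobians are strictly upper triangular", {
  skip_if_not_installed("pracma")
  set.seed(21)
  p <- 4
  enc <- vie_encoder(d = 3, p = p, flow_depth = 2, seed = 9)
  ctx <- matrix(rnorm(enc$context_dim), 1)
  for (t in 1:2) {
    for (rep in 1:3) {
      z <- rnorm(p)
      for (head in c("mu", "s_raw")) {
        J <- pracma::jacobian(function(zv) {
          cond <- vie:::conditioner_forward(matrix(zv, 1), ctx,
                                            enc$params$flows[[t]], enc$masks)
          as.numeric(ad_value(cond[[head]]))
        }, z)
        expect_lt(max(abs(J[lower.tri(J, diag = TRUE)])), 1e-8)
      }
    }
  }
})

test_that("the flow inverts: z0 is recovered from z_T", {
  set.seed(4)
  enc <- vie_encoder(d = 5, p = 4, flow_depth = 3, seed = 13)
  x <- matrix(rnorm(30), 6)
  eo <- encode(x, enc)
  path <- flow_forward(matrix(rnorm(24), 6), eo, enc)
  z0 <- flow_invert(ad_value(path$z), ad_value(eo$context), enc)
  expect_lt(max(abs(z0 - path$z_steps[[1]])), 1e-6)
})

test_that("flow samples integrate like exp(log_q) in one dimension", {
  # E[f(z)] under flow samples vs numerical integral of f * exp(log_q)
  set.seed(77)
  x <- matrix(rnorm(3), 1)
  for (T in c(0L, 1L, 2L)) {
    enc <- vie_encoder(d = 3, p = 1, flow_depth = T, seed = 30 + T)
    eo <- encode(x, enc)
    n <- 100000
    path <- flow_forward(matrix(rnorm(n), n), list(
      mu0 = matrix(rep(ad_value(eo$mu0), n), n),
      sigma0 = matrix(rep(ad_value(eo$sigma0), n), n),
      context = matrix(rep(ad_value(eo$context), each = n), n)), enc)
    zs <- as.numeric(ad_value(path$z))
    f <- function(z) tanh(z)                     # bounded test function
    mc <- mean(f(zs))
    # density of z at a point via log_q of a 1-row path is awkward to scan;
    # use the inverse map: density q(z) = phi(z0(z)) / |dz/dz0|
    grid <- seq(min(zs) - 1, max(zs) + 1, length.out = 2001)
    z0g <- flow_invert(matrix(grid, ncol = 1),
                       matrix(rep(ad_value(eo$context), each = length(grid)),
                              length(grid)), enc)
    dz0 <- c(diff(z0g[, 1]) / diff(grid))
    dens <- dnorm(z0g[, 1], ad_value(eo$mu0)[1], ad_value(eo$sigma0)[1]) *
      c(dz0[1], dz0)
    quad <- sum(f(grid) * dens * c(diff(grid)[1], diff(grid)))
    expect_lt(abs(mc - quad), 4 * sd(f(zs)) / sqrt(n) + 2e-3)
  }
})

test_that("the implicit sampler is seeded, stochastic, and density-free", {
  enc <- vie_implicit_encoder(d = 4, p = 3, seed = 8)
  x <- matrix(rnorm(12), 3)
  a <- implicit_sample(x, enc, seed = 5)
  b <- implicit_sample(x, enc, seed = 5)
  expect_identical(ad_value(a$z), ad_value(b$z))
  cc <- implicit_sample(x, enc, seed = 6)
  expect_gt(stats::var(as.numeric(ad_value(a$z) - ad_value(cc$z))), 0)
  expect_error(flow_log_q(a), "unavailable")
})
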