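# Objective wiring, mini-max training loop, prediction, checkpoints.

test_that("variant wiring reproduces the ablation architecture grid", {
  grid <- list(
    vae = list(prior = "gaussian", encoder = "gaussian",
               decoder = "mlp", prior_match = TRUE),
    vae_gpd = list(prior = "mixed_gpd", encoder = "gaussian",
                   decoder = "amnn", prior_match = FALSE),
    iaf_gpd = list(prior = "mixed_gpd", encoder = "iaf",
                   decoder = "amnn", prior_match = FALSE),
    fenchel_gpd = list(prior = "mixed_gpd", encoder = "implicit",
                       decoder = "amnn", prior_match = TRUE),
    vie = list(prior = "mixed_gpd", encoder = "iaf",
               decoder = "amnn", prior_match = TRUE))
  for (v in names(grid)) expect_identical(variant_wiring(v), grid[[v]])
  expect_error(variant_wiring("boost"))
  # the assembled components match the wiring
  m <- vie:::new_vie_model(4, tiny_config("fenchel_gpd"))
  expect_s3_class(m$prior, "mixed_gpd_prior")
  expect_identical(m$encoder$kind, "implicit")
  expect_s3_class(m$decoder, "amnn_params")
  expect_false(is.null(m$critic))
  m2 <- vie:::new_vie_model(4, tiny_config("vae_gpd"))
  expect_identical(m2$encoder$flow_depth, 0L)
  expect_true(is.null(m2$critic))
})

test_that("the objective reduces to the Bernoulli CLL log-likelihood at beta = 0", {
  set.seed(2)
  n <- 400; prev <- 0.3
  y <- rbinom(n, 1, prev)
  x <- matrix(rnorm(n * 3), n)
  cfg <- tiny_config("vie", beta = 0)
  m <- vie:::new_vie_model(3, cfg, prevalence = mean(y))
  # bias-only decoder at gamma = cloglog(prevalence)
  m$decoder$alpha[] <- 0
  gamma <- log(-log(1 - mean(y)))
  m$decoder$gamma[] <- gamma
  got <- objective_psi(x, y, m, seed = 5)
  want <- mean(ifelse(y == 1, log(1 - exp(-exp(gamma))), -exp(gamma)))
  expect_equal(got, want, tolerance = 1e-12)
  # reproducible under a fixed seed
  expect_identical(objective_psi(x, y, m, seed = 5), got)
})

test_that("every component receives gradient in the full wiring", {
  set.seed(3)
  cfg <- tiny_config("vie")
  n <- 64
  x <- matrix(rnorm(n * 4), n); y <- rbinom(n, 1, 0.2)
  m <- vie:::new_vie_model(4, cfg, prevalence = 0.2)
  tp <- vie:::ad_tape()
  w_enc <- vie:::wrap_params(m$encoder$params, tp)
  dec_p <- m$decoder[c("integrands", "alpha", "gamma")]
  w_rest <- vie:::wrap_params(list(dec = dec_p,
                                   prior = vie:::prior_leaves(m$prior)), tp)
  ps <- vie:::psi_forward(x, y, m, w_enc, w_rest$dec, w_rest$prior, S = 1)
  u01 <- matrix(runif(n * cfg$latent_dim), n)
  pz <- vie:::mixture_rsample_ad(u01, w_rest$prior$xi, w_rest$prior$sigma_raw,
                                 cfg$u)
  # critic gradient: wrap the critic too and differentiate Gamma through it
  w_cr <- vie:::wrap_params(m$critic$params, tp)
  gam <- fenchel_gamma(ps$z, pz, m$critic, params = w_cr)
  obj <- vie:::ad_sub(ps$psi, vie:::ad_mul(cfg$lambda, gam))
  vie:::ad_backward(obj)
  gnorm <- function(w) max(abs(unlist(vie:::param_map(vie:::ad_grad, w))))
  expect_gt(gnorm(w_enc), 0)                      # phi
  expect_gt(gnorm(w_rest$dec), 0)                 # theta
  expect_gt(gnorm(w_rest$prior), 0)               # psi (tail parameters)
  expect_gt(gnorm(w_cr), 0)                       # omega
})

test_that("training runs, improves a separable toy problem, and is reproducible", {
  set.seed(4)
  n <- 600
  x <- matrix(rnorm(n * 3), n)
  y <- as.integer(x[, 1] + 0.5 * rnorm(n) > 0.8)
  cfg <- tiny_config("vae", beta = 0.01, max_epochs = 6, patience = 6,
                     lr = 1e-2)
  fit <- vie_train(x[1:400, ], y[1:400], x[401:600, ], y[401:600], cfg)
  expect_s3_class(fit, "vie_model")
  h <- fit$history
  expect_gt(h$objective[nrow(h)], h$objective[1])          # loss improves
  expect_gt(max(h$val_auc, na.rm = TRUE), 0.7)             # learns the signal
  fit2 <- vie_train(x[1:400, ], y[1:400], x[401:600, ], y[401:600], cfg)
  expect_identical(fit$history, fit2$history)              # determinism
  expect_identical(predict_risk(fit, x[401:410, ], seed = 3),
                   predict_risk(fit2, x[401:410, ], seed = 3))
  expect_error(vie_train(x[1:50, ], rep(0, 50), x[1:10, ], y[1:10], cfg),
               "minority")
})

test_that("prediction contracts: seeding, constant decoder, dimension guard", {
  sim <- tiny_sim(n = 600, d = 4, rate = 0.15, seed = 9)
  cfg <- tiny_config("vie", max_epochs = 2, patience = 2)
  fit <- vie_train(sim$ds$X[sim$sp$train, ], sim$ds$y[sim$sp$train],
                   sim$ds$X[sim$sp$val, ], sim$ds$y[sim$sp$val], cfg)
  xt <- sim$ds$X[sim$sp$test, ]
  expect_identical(predict_risk(fit, xt, s_eval = 1, seed = 7),
                   predict_risk(fit, xt, s_eval = 1, seed = 7))
  expect_error(predict_risk(fit, xt[, 1:2]), "dimension")
  # bias-only decoder gives constant risk
  fit$decoder$alpha[] <- 0
  fit$decoder$gamma[] <- -2
  expect_equal(unique(predict_risk(fit, xt, s_eval = 3, seed = 1)),
               1 - exp(-exp(-2)))
})

test_that("checkpoints round-trip to identical predictions", {
  sim <- tiny_sim(n = 500, d = 4, rate = 0.15, seed = 11)
  for (v in c("vie", "vae", "fenchel_gpd")) {
    cfg <- tiny_config(v, max_epochs = 2, patience = 2)
    fit <- vie_train(sim$ds$X[sim$sp$train, ], sim$ds$y[sim$sp$train],
                     sim$ds$X[sim$sp$val, ], sim$ds$y[sim$sp$val], cfg)
    f <- tempfile(fileext = ".json")
    vie_save(fit, f)
    back <- vie_load(f)
    xt <- sim$ds$X[sim$sp$test[1:40], ]
    expect_identical(predict_risk(fit, xt, s_eval = 4, seed = 2),
                     predict_risk(back, xt, s_eval = 4, seed = 2))
    expect_identical(back$config$variant, v)
    unlink(f)
  }
})

test_that("predicted risk rises along positive-direction latent coordinates", {
  set.seed(5)
  am <- amnn_params(3, seed = 21)
  # weights small and bias negative so the inverse link stays unsaturated
  am$alpha <- matrix(c(0.12, 0.04, 0.2), 1, 3)
  am$gamma <- matrix(-7, 1, 1)
  base <- c(-0.5, 0.2, 0.1)
  for (j in 1:3) {
    zg <- t(vapply(seq(-2, 2, length.out = 9), function(v) {
      z <- base; z[j] <- v; z
    }, numeric(3)))
    expect_true(all(diff(predicted_risk(zg, am)) > 0))
  }
})
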