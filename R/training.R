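# Model assembly and training: the augmented objective Psi_beta - lambda*Gamma,
# the alternating mini-max schedule with extra encoder updates (posterior-lag
# compensation), the ablation wiring grid, prediction, and checkpoints.

VIE_VARIANTS <- c("vae", "vae_gpd", "iaf_gpd", "fenchel_gpd", "vie")

#' Training configuration
#'
#' @param variant model wiring; one of \code{"vae"} (Gaussian prior,
#'   Gaussian encoder, MLP decoder, prior match), \code{"vae_gpd"} (mixed
#'   GPD prior, Gaussian encoder, AMNN), \code{"iaf_gpd"} (adds the IAF
#'   encoder), \code{"fenchel_gpd"} (implicit encoder, Fenchel match only),
#'   \code{"vie"} (mixed GPD prior + IAF + AMNN + Fenchel match).
#' @param beta weight of the per-datum KL term, \eqn{\beta \ge 0}. Because
#'   the objective carries no covariate-reconstruction term, the label
#'   log-likelihood is of order the event prevalence while the KL is order
#'   one; a weight near 1 collapses the posterior onto the prior in the
#'   rare-event regime, so the default is small.
#' @param lambda weight of the aggregated-posterior Fenchel penalty,
#'   \eqn{\lambda \ge 0}.
#' @param latent_dim latent dimensionality \code{p}.
#' @param flow_depth IAF steps \code{T} (ignored by non-IAF encoders).
#' @param mc_samples posterior Monte-Carlo samples per datum in training.
#' @param encoder_extra_steps extra encoder-only ascent steps per joint
#'   step (posterior-lag compensation).
#' @param critic_steps critic ascent steps per joint step.
#' @param lr,lr_critic learning rates (Adam) for the model and the critic.
#' @param batch_size minibatch size.
#' @param max_epochs,patience epoch budget and early-stopping patience on
#'   validation AUPRC.
#' @param u tail threshold of the mixed GPD prior.
#' @param enc_hidden,context_dim,cond_hidden,integrand_hidden,critic_hidden,
#'   dec_hidden network widths.
#' @param n_grid,lower_end AMNN quadrature intervals and lower limit.
#' @param s_eval posterior draws averaged at prediction time.
#' @param val_s_eval posterior draws for per-epoch validation monitoring.
#' @param seed integer seed controlling initialization and training noise.
#' @return object of class \code{vie_config}.
#' @export
vie_config <- function(variant = "vie", beta = 0.01, lambda = 0.1,
                       latent_dim = 10L, flow_depth = 2L, mc_samples = 1L,
                       encoder_extra_steps = 5L, critic_steps = 1L,
                       lr = 1e-3, lr_critic = 1e-4, batch_size = 256L,
                       max_epochs = 50L, patience = 10L,
                       u = stats::qnorm(0.99),
                       enc_hidden = 32L, context_dim = 8L, cond_hidden = 24L,
                       integrand_hidden = 16L, critic_hidden = 64L,
                       dec_hidden = 32L, n_grid = 64L, lower_end = -10,
                       s_eval = 20L, val_s_eval = 5L, seed = 1L) {
  variant <- match.arg(variant, VIE_VARIANTS)
  stopifnot(beta >= 0, lambda >= 0, latent_dim >= 1, flow_depth >= 0,
            mc_samples >= 1, encoder_extra_steps >= 0, critic_steps >= 0,
            batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(as.list(environment()), class = "vie_config")
}

#' Component wiring of each model variant
#'
#' Returns which prior, encoder and decoder a variant uses and whether the
#' aggregated posterior is matched to the prior.
#'
#' @param variant one of the five variant names.
#' @return list with \code{prior}, \code{encoder}, \code{decoder},
#'   \code{prior_match}.
#' @export
variant_wiring <- function(variant) {
  switch(match.arg(variant, VIE_VARIANTS),
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
}

# Assemble untrained components for a wiring.
new_vie_model <- function(d, config, prevalence = 0.1) {
  wiring <- variant_wiring(config$variant)
  p <- config$latent_dim
  gamma0 <- log(-log(1 - min(max(prevalence, 1e-4), 0.99)))
  prior <- if (wiring$prior == "gaussian") gaussian_prior(p)
           else mixed_gpd_prior(p, u = config$u, xi = 0.1, sigma = 1)
  encoder <- switch(wiring$encoder,
    gaussian = vie_encoder(d, p, flow_depth = 0L, hidden = config$enc_hidden,
                           context_dim = config$context_dim,
                           cond_hidden = config$cond_hidden,
                           seed = derive_seed(config$seed, 11)),
    iaf = vie_encoder(d, p, flow_depth = config$flow_depth,
                      hidden = config$enc_hidden,
                      context_dim = config$context_dim,
                      cond_hidden = config$cond_hidden,
                      seed = derive_seed(config$seed, 11)),
    implicit = vie_implicit_encoder(d, p, hidden = config$enc_hidden,
                                    seed = derive_seed(config$seed, 11)))
  decoder <- if (wiring$decoder == "amnn")
    amnn_params(p, hidden = config$integrand_hidden,
                lower_end = config$lower_end, n_grid = config$n_grid,
                gamma = gamma0, seed = derive_seed(config$seed, 12))
  else
    mlp_decoder_params(p, hidden = config$dec_hidden, gamma = gamma0,
                       seed = derive_seed(config$seed, 12))
  critic <- if (wiring$prior_match)
    vie_critic(p, hidden = config$critic_hidden,
               seed = derive_seed(config$seed, 13))
  structure(list(config = config, wiring = wiring, d = as.integer(d),
                 prior = prior, encoder = encoder, decoder = decoder,
                 critic = critic, center = rep(0, d), scale = rep(1, d),
                 history = NULL),
            class = "vie_model")
}

# Posterior sample + objective pieces for one minibatch. `enc_p`, `dec_p`
# and `prior_p` may be tape-wrapped (training) or plain (evaluation);
# draws come from the current RNG stream.
psi_forward <- function(x, y, model, enc_p, dec_p, prior_p, S = 1L) {
  n <- nrow(ad_value(x))
  p <- model$config$latent_dim
  ll_acc <- NULL; kl_acc <- NULL; z_last <- NULL
  for (s in seq_len(S)) {
    if (model$wiring$encoder == "implicit") {
      eps <- matrix(stats::rnorm(n * p), n)
      path <- implicit_sample(x, model$encoder, params = enc_p, eps = eps)
      z <- path$z
      kl <- NULL
    } else {
      eps <- matrix(stats::rnorm(n * p), n)
      eo <- encode(x, model$encoder, params = enc_p)
      path <- flow_forward(eps, eo, model$encoder, params = enc_p)
      z <- path$z
      kl <- if (model$wiring$prior == "gaussian") {
        # closed-form diagonal-Gaussian KL (exact only when T = 0)
        ad_mean(ad_rowsums(ad_mul(0.5,
          ad_sub(ad_add(ad_mul(eo$mu0, eo$mu0), ad_mul(eo$sigma0, eo$sigma0)),
                 ad_add(1, ad_mul(2, ad_log(eo$sigma0)))))))
      } else {
        lp <- ad_rowsums(mixture_log_pdf_ad(z, prior_p$xi, prior_p$sigma_raw,
                                            model$config$u))
        ad_mean(ad_sub(path$log_q, lp))
      }
    }
    a <- decoder_score(z, model$decoder, dec_p)
    ll <- ad_mean(cll_log_lik(y, a))
    ll_acc <- if (is.null(ll_acc)) ll else ad_add(ll_acc, ll)
    if (!is.null(kl)) kl_acc <- if (is.null(kl_acc)) kl else ad_add(kl_acc, kl)
    z_last <- z
  }
  ll_mean <- ad_mul(ll_acc, 1 / S)
  kl_mean <- if (!is.null(kl_acc)) ad_mul(kl_acc, 1 / S)
  psi <- if (is.null(kl_mean)) ll_mean
         else ad_sub(ll_mean, ad_mul(model$config$beta, kl_mean))
  list(psi = psi, z = z_last, ll = ll_mean, kl = kl_mean)
}

#' Monte-Carlo estimate of the per-datum objective
#'
#' \eqn{\Psi_\beta = E_{q(z|x)}[\log p(y|z)] - \beta\,KL(q(z|x)\|p(z))},
#' estimated with \code{mc_samples} posterior draws. For the Gaussian-prior
#' (vanilla VAE) wiring the KL is closed form; for the implicit encoder the
#' per-datum KL is omitted (no tractable posterior density).
#'
#' @param x feature matrix on the model's standardized scale (use
#'   raw features only for models trained without standardization).
#' @param y binary labels.
#' @param model a \code{vie_model}.
#' @param seed integer seed for the posterior draws.
#' @return scalar objective value (to be maximized).
#' @export
objective_psi <- function(x, y, model, seed = 1L) {
  y <- check_labels(y, rep(0, nrow(as.matrix(x))))
  prior_p <- prior_leaves(model$prior)
  dec_p <- NULL
  with_seed(seed, {
    ps <- psi_forward(as.matrix(x), y, model, model$encoder$params, dec_p,
                      prior_p, S = model$config$mc_samples)
    as.numeric(ad_value(ps$psi))
  })
}

prior_leaves <- function(prior) {
  if (!inherits(prior, "mixed_gpd_prior")) return(NULL)
  list(xi = matrix(prior$xi, 1L), sigma_raw = matrix(prior$sigma_raw, 1L))
}

#' Fit a model by mini-max variational training
#'
#' Alternates, per minibatch: (1) \code{critic_steps} ascent steps of the
#' critic on the Fenchel objective; (2) one joint ascent step of encoder,
#' decoder and prior tail parameters on
#' \eqn{\Psi_\beta - \lambda\,\Gamma}; (3) \code{encoder_extra_steps}
#' encoder-only ascent steps on \eqn{\Psi_\beta}. Features are
#' standardized to zero mean / unit variance with training-split
#' statistics. Training stops early when validation AUPRC has not improved
#' for \code{patience} epochs; the best checkpoint is returned.
#'
#' @param x,y training features (matrix/data frame) and binary labels.
#' @param x_val,y_val validation split (disjoint from training).
#' @param config a [vie_config()].
#' @param verbose print one line per epoch.
#' @return object of class \code{vie_model} with a \code{history} data
#'   frame (epoch, objective, val_auc, val_auprc).
#' @export
vie_train <- function(x, y, x_val, y_val, config = vie_config(),
                      verbose = FALSE) {
  x <- as.matrix(x); x_val <- as.matrix(x_val)
  y <- check_labels(y, numeric(nrow(x)))
  y_val <- check_labels(y_val, numeric(nrow(x_val)))
  if (sum(y == 1) == 0L) stop("training split has no minority-class (y=1) examples")
  if (sum(y == 0) == 0L) stop("training split has no majority-class (y=0) examples")

  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd); scl[scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  xvs <- sweep(sweep(x_val, 2, center), 2, scl, "/")

  model <- new_vie_model(ncol(x), config, prevalence = mean(y))
  model$center <- center; model$scale <- scl

  enc_p <- model$encoder$params
  dec_p <- if (model$wiring$decoder == "amnn")
    model$decoder[c("integrands", "alpha", "gamma")] else list(net = model$decoder$net)
  prior_p <- prior_leaves(model$prior)
  rest_p <- if (is.null(prior_p)) list(dec = dec_p) else
    list(dec = dec_p, prior = prior_p)

  st_enc <- adam_init(enc_p)
  st_rest <- adam_init(rest_p)
  critic <- model$critic
  st_critic <- if (!is.null(critic)) critic_state(critic)
  match_on <- model$wiring$prior_match && config$lambda > 0

  set.seed(config$seed)
  n <- nrow(xs); p <- config$latent_dim
  best <- list(metric = -Inf)
  hist <- list()
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    obj_sum <- 0; n_b <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      bi <- idx[start:min(start + config$batch_size - 1L, n)]
      if (length(bi) < 2L) next
      xb <- xs[bi, , drop = FALSE]; yb <- y[bi]
      m <- length(bi)

      sync_model <- function() {
        model$encoder$params <- enc_p
        if (model$wiring$decoder == "amnn")
          model$decoder[c("integrands", "alpha", "gamma")] <- rest_p$dec
        else model$decoder$net <- rest_p$dec$net
        if (!is.null(rest_p$prior)) {
          model$prior$xi <- as.numeric(rest_p$prior$xi)
          model$prior$sigma_raw <- as.numeric(rest_p$prior$sigma_raw)
        }
        model
      }

      # (1) critic ascent on Gamma, samples detached
      if (match_on && config$critic_steps > 0) {
        model <- sync_model()
        qz <- sample_posterior(xb, model)
        pz <- mixture_sample(m, model$prior)
        for (cs in seq_len(config$critic_steps)) {
          up <- critic_step(qz, pz, critic, st_critic, config$lr_critic)
          critic <- up$critic; st_critic <- up$state
        }
      }

      # (2) one joint ascent step on Psi - lambda * Gamma
      model <- sync_model()
      tp <- ad_tape()
      w_enc <- wrap_params(enc_p, tp)
      w_rest <- wrap_params(rest_p, tp)
      ps <- psi_forward(xb, yb, model, w_enc, w_rest$dec, w_rest$prior,
                        S = config$mc_samples)
      obj <- ps$psi
      if (match_on) {
        pzn <- if (model$wiring$prior == "gaussian")
          matrix(stats::rnorm(m * p), m)
        else
          mixture_rsample_ad(matrix(stats::runif(m * p), m),
                             w_rest$prior$xi, w_rest$prior$sigma_raw,
                             config$u)
        gam <- fenchel_gamma(ps$z, pzn, critic)
        obj <- ad_sub(obj, ad_mul(config$lambda, gam))
      }
      ad_backward(obj)
      ue <- adam_step(enc_p, collect_grads(w_enc), st_enc, config$lr)
      enc_p <- ue$params; st_enc <- ue$state
      ur <- adam_step(rest_p, collect_grads(w_rest), st_rest, config$lr)
      rest_p <- ur$params; st_rest <- ur$state
      obj_sum <- obj_sum + as.numeric(ad_value(obj)); n_b <- n_b + 1L

      # (3) extra encoder-only ascent steps on Psi (posterior lag)
      for (ks in seq_len(config$encoder_extra_steps)) {
        model <- sync_model()
        tp <- ad_tape()
        w_enc <- wrap_params(enc_p, tp)
        ps <- psi_forward(xb, yb, model, w_enc, rest_p$dec, rest_p$prior,
                          S = config$mc_samples)
        ad_backward(ps$psi)
        ue <- adam_step(enc_p, collect_grads(w_enc), st_enc, config$lr)
        enc_p <- ue$params; st_enc <- ue$state
      }
      model$encoder$params <- enc_p
    }

    # validation monitoring
    model <- local({
      model$encoder$params <- enc_p
      if (model$wiring$decoder == "amnn")
        model$decoder[c("integrands", "alpha", "gamma")] <- rest_p$dec
      else model$decoder$net <- rest_p$dec$net
      if (!is.null(rest_p$prior)) {
        model$prior$xi <- as.numeric(rest_p$prior$xi)
        model$prior$sigma_raw <- as.numeric(rest_p$prior$sigma_raw)
      }
      model$critic <- critic
      model
    })
    vrisk <- predict_std(model, xvs, config$val_s_eval,
                         seed = derive_seed(config$seed, 500 + epoch))
    vauc <- if (length(unique(y_val)) == 2L) auc(vrisk, y_val) else NA_real_
    vpr <- if (sum(y_val) > 0) auprc(vrisk, y_val) else NA_real_
    hist[[epoch]] <- data.frame(epoch = epoch, objective = obj_sum / max(n_b, 1L),
                                val_auc = vauc, val_auprc = vpr)
    if (verbose)
      message(sprintf("epoch %3d  obj %8.4f  val AUC %.3f  val AUPRC %.3f",
                      epoch, obj_sum / max(n_b, 1L), vauc, vpr))
    metric <- if (is.na(vpr)) obj_sum / max(n_b, 1L) else vpr
    if (metric > best$metric + 1e-12) {
      best <- list(metric = metric, enc = enc_p, rest = rest_p,
                   critic = critic, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  # restore best checkpoint
  model$encoder$params <- best$enc %||% enc_p
  rb <- if (is.null(best$rest)) rest_p else best$rest
  if (model$wiring$decoder == "amnn")
    model$decoder[c("integrands", "alpha", "gamma")] <- rb$dec
  else model$decoder$net <- rb$dec$net
  if (!is.null(rb$prior)) {
    model$prior$xi <- as.numeric(rb$prior$xi)
    model$prior$sigma_raw <- as.numeric(rb$prior$sigma_raw)
  }
  model$critic <- best$critic %||% critic
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best$epoch %||% NA_integer_
  model
}

# posterior draw (values only) on the standardized scale
sample_posterior <- function(xs, model) {
  n <- nrow(xs); p <- model$config$latent_dim
  eps <- matrix(stats::rnorm(n * p), n)
  if (model$wiring$encoder == "implicit") {
    ad_value(implicit_sample(xs, model$encoder, eps = eps)$z)
  } else {
    eo <- encode(xs, model$encoder)
    ad_value(flow_forward(eps, eo, model$encoder)$z)
  }
}

# prediction on already-standardized features
predict_std <- function(model, xs, s_eval, seed) {
  n <- nrow(xs)
  with_seed(seed, {
    acc <- numeric(n)
    for (s in seq_len(s_eval)) {
      z <- sample_posterior(xs, model)
      acc <- acc + predicted_risk(z, model$decoder)
    }
    acc / s_eval
  })
}

#' Posterior-averaged predicted risk
#'
#' Averages the decoder risk \eqn{1 - \exp(-e^{H(z)})} over \code{s_eval}
#' posterior draws per row; deterministic given \code{seed}.
#'
#' @param model a fitted \code{vie_model}.
#' @param x_new feature matrix on the original (unstandardized) scale.
#' @param s_eval number of posterior draws.
#' @param seed integer seed.
#' @return event probability per row.
#' @export
predict_risk <- function(model, x_new, s_eval = model$config$s_eval, seed = 1L) {
  x_new <- as.matrix(x_new)
  if (ncol(x_new) != model$d)
    stop("feature dimension mismatch: model expects ", model$d, " columns")
  xs <- sweep(sweep(x_new, 2, model$center), 2, model$scale, "/")
  predict_std(model, xs, s_eval, seed)
}

#' @export
predict.vie_model <- function(object, newdata, s_eval = object$config$s_eval,
                              seed = 1L, ...) {
  predict_risk(object, newdata, s_eval, seed)
}

#' @export
print.vie_model <- function(x, ...) {
  w <- x$wiring
  cat(sprintf("vie model  variant=%s  (prior=%s, encoder=%s, decoder=%s, match=%s)\n",
              x$config$variant, w$prior, w$encoder, w$decoder, w$prior_match))
  cat(sprintf("  d=%d  p=%d  trained %s epochs (best %s)\n", x$d,
              x$config$latent_dim,
              if (is.null(x$history)) 0 else nrow(x$history),
              x$best_epoch %||% NA))
  invisible(x)
}

# --- checkpoint --------------------------------------------------------------

ser_obj <- function(x) {
  if (is.environment(x)) return(NULL)            # transient caches
  if (is.matrix(x))
    return(list(`_mat` = TRUE, dim = dim(x), data = as.numeric(x)))
  if (is.list(x)) {
    cls <- class(x)
    x <- x[!vapply(x, is.environment, logical(1))]
    out <- lapply(x, ser_obj)
    if (!identical(cls, "list")) out[["_class"]] <- cls
    return(out)
  }
  if (is.function(x)) stop("cannot serialize functions")
  x
}

deser_obj <- function(x) {
  if (!is.list(x)) return(x)
  if (isTRUE(x[["_mat"]]))
    return(matrix(as.numeric(x$data), x$dim[1], x$dim[2]))
  cls <- x[["_class"]]
  x[["_class"]] <- NULL
  out <- lapply(x, deser_obj)
  if (!is.null(cls)) class(out) <- unlist(cls)
  out
}

#' Save a fitted model as a self-describing text checkpoint
#'
#' JSON with full floating-point precision; [vie_load()] reproduces
#' identical predictions.
#'
#' @param model a \code{vie_model}.
#' @param path output file.
#' @export
vie_save <- function(model, path) {
  hist <- model$history
  model$history <- NULL
  obj <- ser_obj(unclass(model))
  obj$`_class` <- NULL
  payload <- list(format = "vie-checkpoint", version = 1L,
                  model = obj,
                  history = if (!is.null(hist)) as.list(hist))
  # I(17) significant digits: doubles survive the text round-trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a checkpoint written by [vie_save()]
#'
#' @param path checkpoint file.
#' @return a \code{vie_model}.
#' @export
vie_load <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE)
  if (!identical(payload$format, "vie-checkpoint"))
    stop("not a vie checkpoint: ", path)
  model <- deser_obj(payload$model)
  model$center <- as.numeric(model$center)
  model$scale <- as.numeric(model$scale)
  if (!is.null(model$prior$xi)) {
    model$prior$xi <- as.numeric(model$prior$xi)
    model$prior$sigma_raw <- as.numeric(model$prior$sigma_raw)
  }
  if (inherits(model$decoder, "amnn_params"))
    model$decoder$cache_env <- new.env(parent = emptyenv())
  model$history <- if (!is.null(payload$history))
    as.data.frame(lapply(payload$history, unlist))
  class(model) <- "vie_model"
  model
}
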