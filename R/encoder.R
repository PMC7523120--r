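# Approximate posterior q(z|x): a feed-forward Gaussian base encoder followed
# by T inverse-autoregressive-flow (IAF) steps with exact log-density, plus a
# density-free implicit sampler used by the Fenchel-only ablation.

#' Construct a flow encoder
#'
#' Builds the parameters of the amortized posterior: an initial network
#' mapping \code{x} to a diagonal-Gaussian base \eqn{(\mu_0, \sigma_0)} and a
#' context vector, followed by \code{flow_depth} IAF steps
#' \eqn{z_t = \mu_t + \sigma_t \odot z_{t-1}} whose conditioners are masked
#' autoregressive networks over \eqn{(z_{t-1}, \mathrm{context})}. With
#' \code{flow_depth = 0} the posterior is the diagonal Gaussian itself.
#'
#' @param d input (feature) dimension.
#' @param p latent dimension.
#' @param flow_depth number of flow steps \eqn{T \ge 0}.
#' @param hidden width of the base encoder's hidden layer.
#' @param context_dim length of the conditioning vector passed to every
#'   flow step.
#' @param cond_hidden width of the two hidden layers in each masked
#'   conditioner.
#' @param seed integer seed for parameter initialization.
#' @return an object of class \code{vie_encoder}.
#' @export
vie_encoder <- function(d, p, flow_depth = 2L, hidden = 32L,
                        context_dim = 8L, cond_hidden = 24L, seed = 1L) {
  stopifnot(d >= 1, p >= 1, flow_depth >= 0)
  with_seed(seed, {
    enc <- init_mlp(c(d, hidden, 2L * p + context_dim))
    flows <- if (flow_depth > 0)
      lapply(seq_len(flow_depth),
             function(t) init_conditioner(p, context_dim, cond_hidden))
    else list()
    structure(list(
      kind = "iaf", d = as.integer(d), p = as.integer(p),
      flow_depth = as.integer(flow_depth),
      context_dim = as.integer(context_dim),
      masks = made_masks(p, context_dim, cond_hidden, cond_hidden),
      params = list(enc = enc, flows = flows)
    ), class = "vie_encoder")
  })
}

#' Construct an implicit (density-free) encoder
#'
#' A feed-forward sampler \eqn{z = f(x, \epsilon)} with injected Gaussian
#' noise. It has no tractable log-density, so models using it are trained
#' with the Fenchel aggregated-posterior penalty only.
#'
#' @inheritParams vie_encoder
#' @export
vie_implicit_encoder <- function(d, p, hidden = 32L, seed = 1L) {
  with_seed(seed, {
    structure(list(
      kind = "implicit", d = as.integer(d), p = as.integer(p),
      flow_depth = 0L,
      params = list(enc = init_mlp(c(d + p, hidden, p)))
    ), class = "vie_encoder")
  })
}

#' Encode features to the posterior base distribution
#'
#' @param x numeric matrix (rows = observations) or a single feature vector.
#' @param encoder a [vie_encoder()].
#' @param params optionally, tape-wrapped parameters (training path);
#'   defaults to the encoder's stored numeric parameters.
#' @return list with \code{mu0}, \code{sigma0} (positive, via softplus) and
#'   \code{context}, each with one row per observation.
#' @export
encode <- function(x, encoder, params = NULL) {
  stopifnot(inherits(encoder, "vie_encoder"), encoder$kind == "iaf")
  x <- check_features(x, encoder$d)
  params <- params %||% encoder$params
  out <- mlp_forward(x, params$enc)
  p <- encoder$p
  list(mu0 = ad_cols(out, 1:p),
       sigma0 = ad_softplus(ad_cols(out, (p + 1L):(2L * p))),
       context = ad_tanh(ad_cols(out, (2L * p + 1L):(2L * p + encoder$context_dim))))
}

check_features <- function(x, d) {
  if (is_advar(x)) return(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != d) stop("feature dimension mismatch: expected ", d,
                         " columns, got ", ncol(x))
  if (any(!is.finite(x))) stop("features must be finite (no NA/NaN/Inf)")
  x
}

#' Run the flow forward from base noise
#'
#' Applies \eqn{z_0 = \mu_0 + \sigma_0 \odot \epsilon} and then each IAF step
#' \eqn{z_t = \mu_t + \sigma_t \odot z_{t-1}}, with
#' \eqn{\sigma_t = \mathrm{sigmoid}(s_t + 1.5)} from the masked conditioner.
#' The exact posterior log-density of \eqn{z_T} is accumulated alongside:
#' \deqn{\log q(z|x) = -\sum_j \left(\tfrac12 \epsilon_j^2 +
#'   \tfrac12\log(2\pi) + \sum_{t=0}^{T} \log \sigma_{t,j}\right).}
#'
#' @param eps an \code{n x p} matrix of standard-normal base draws.
#' @param enc output of [encode()].
#' @param encoder the [vie_encoder()].
#' @param params optional tape-wrapped parameters.
#' @return list of class \code{flow_path}: \code{z} (final sample),
#'   \code{z_steps} (list \eqn{z_0 \ldots z_T} of values), \code{log_q}
#'   (per-row exact log-density), \code{log_sigma_sums}, \code{eps}.
#' @export
flow_forward <- function(eps, enc, encoder, params = NULL) {
  stopifnot(encoder$kind == "iaf")
  params <- params %||% encoder$params
  epsv <- ad_value(eps)
  z <- ad_add(enc$mu0, ad_mul(enc$sigma0, eps))
  log_sig <- ad_log(enc$sigma0)                  # n x p running sum of log sigma_t
  z_steps <- list(ad_value(z))
  if (encoder$flow_depth > 0) {
    for (t in seq_len(encoder$flow_depth)) {
      cond <- conditioner_forward(z, enc$context, params$flows[[t]],
                                  encoder$masks)
      sig_t <- ad_sigmoid(ad_add(cond$s_raw, 1.5))
      z <- ad_add(cond$mu, ad_mul(sig_t, z))
      log_sig <- ad_add(log_sig, ad_log(sig_t))
      z_steps[[t + 1L]] <- ad_value(z)
    }
  }
  resid <- if (is_advar(eps)) ad_mul(eps, eps) else epsv * epsv
  lq <- ad_neg(ad_rowsums(ad_add(ad_add(ad_mul(0.5, resid),
                                        0.5 * log(2 * pi)),
                                 log_sig)))
  structure(list(z = z, z_steps = z_steps, log_q = lq,
                 log_sigma_sums = log_sig, eps = epsv, implicit = FALSE),
            class = "flow_path")
}

#' Exact posterior log-density of a flow path
#'
#' @param path a \code{flow_path} from [flow_forward()].
#' @return per-row log-density (numeric vector).
#' @export
flow_log_q <- function(path) {
  if (isTRUE(path$implicit))
    stop("log-density is unavailable for the implicit encoder")
  as.numeric(ad_value(path$log_q))
}

#' Invert the flow
#'
#' Recovers \eqn{z_0} from \eqn{z_T} by sequential per-dimension inversion of
#' each affine autoregressive step (dimension \code{j} of the conditioner
#' depends only on dimensions \code{> j}, so back-substitution converges in
#' at most \code{p} sweeps; one ordered sweep suffices).
#'
#' @param z_T matrix of final samples.
#' @param context matrix of context vectors (from [encode()]).
#' @param encoder the [vie_encoder()].
#' @return the matrix \eqn{z_0}.
#' @export
flow_invert <- function(z_T, context, encoder) {
  stopifnot(encoder$kind == "iaf")
  z <- as.matrix(z_T)
  for (t in rev(seq_len(encoder$flow_depth))) {
    cp <- encoder$params$flows[[t]]
    zprev <- matrix(0, nrow(z), ncol(z))
    for (j in rev(seq_len(ncol(z)))) {
      cond <- conditioner_forward(zprev, context, cp, encoder$masks)
      sig <- stats::plogis(ad_value(cond$s_raw) + 1.5)
      zprev[, j] <- (z[, j] - ad_value(cond$mu)[, j]) / sig[, j]
    }
    z <- zprev
  }
  z
}

#' Draw from the implicit encoder
#'
#' @param x feature matrix or vector.
#' @param encoder a [vie_implicit_encoder()].
#' @param seed integer seed for the injected noise.
#' @param params optional tape-wrapped parameters.
#' @param eps optionally, pre-drawn noise (overrides \code{seed}).
#' @return a \code{flow_path} whose \code{z} holds the draws and whose
#'   log-density is flagged unavailable.
#' @export
implicit_sample <- function(x, encoder, seed = NULL, params = NULL, eps = NULL) {
  stopifnot(inherits(encoder, "vie_encoder"), encoder$kind == "implicit")
  x <- check_features(x, encoder$d)
  params <- params %||% encoder$params
  n <- nrow(ad_value(x))
  if (is.null(eps)) {
    eps <- if (is.null(seed)) matrix(stats::rnorm(n * encoder$p), n)
           else with_seed(seed, matrix(stats::rnorm(n * encoder$p), n))
  }
  z <- mlp_forward(ad_cbind2(x, eps), params$enc)
  structure(list(z = z, z_steps = list(ad_value(z)), log_q = NULL,
                 eps = eps, implicit = TRUE),
            class = "flow_path")
}
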