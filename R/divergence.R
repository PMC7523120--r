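# The three KL estimators the objective uses: Monte-Carlo KL(q(z|x) || p(z))
# from tractable log-densities, closed-form diagonal-Gaussian KL for the
# vanilla-VAE wiring, and the Fenchel mini-max estimator of the aggregated
# posterior KL(q(z) || p(z)) with a critic network.

#' Monte-Carlo KL divergence from posterior samples
#'
#' Estimates \eqn{KL(q \| p)} as the average of
#' \eqn{\log q(z) - \log p(z)} over samples drawn from \eqn{q} with their
#' exact log-densities (from the flow). Unbiased for the true KL.
#'
#' @param log_q per-sample posterior log-densities.
#' @param z_samples matching samples, \code{n x p}.
#' @param prior a [mixed_gpd_prior()] or [gaussian_prior()].
#' @return scalar estimate.
#' @export
kl_mc <- function(log_q, z_samples, prior) {
  lq <- as.numeric(ad_value(log_q))
  mean(lq - prior_log_pdf(ad_value(z_samples), prior))
}

#' Closed-form diagonal-Gaussian KL to the standard normal
#'
#' \eqn{\sum_j \frac12 (\mu_j^2 + \sigma_j^2 - 1 - 2\log\sigma_j)}; for
#' matrix input the sum is per row.
#'
#' @param mu means (vector, or matrix with rows = observations).
#' @param sigma standard deviations, strictly positive, same shape.
#' @return scalar (vector input) or per-row vector (matrix input).
#' @export
kl_gaussian_closed_form <- function(mu, sigma) {
  if (any(ad_value(sigma) <= 0)) stop("sigma must be strictly positive")
  term <- 0.5 * (mu^2 + sigma^2 - 1 - 2 * log(sigma))
  if (is.matrix(term)) rowSums(term) else sum(term)
}

#' Construct a critic network
#'
#' The critic \eqn{\nu(z;\omega)} of the Fenchel dual KL estimator: a
#' feed-forward network from the latent space to a scalar.
#'
#' @param p latent dimension.
#' @param hidden hidden width (two hidden layers).
#' @param seed integer seed.
#' @return object of class \code{vie_critic}.
#' @export
vie_critic <- function(p, hidden = 64L, seed = 1L) {
  with_seed(seed, {
    structure(list(p = as.integer(p),
                   params = list(net = init_mlp(c(p, hidden, hidden, 1L)))),
              class = "vie_critic")
  })
}

#' Evaluate the critic
#'
#' @param z latent matrix.
#' @param critic a [vie_critic()].
#' @param params optional tape-wrapped parameters.
#' @return critic values, one per row.
#' @export
critic_value <- function(z, critic, params = NULL) {
  params <- params %||% critic$params
  out <- mlp_forward(z, params$net)
  if (is_advar(out)) out else as.numeric(out)
}

# Exponent clamp inside the Fenchel objective.
FENCHEL_CLAMP <- 30

#' Fenchel dual KL objective
#'
#' \deqn{\Gamma(p, q, \nu) = E_{Z \sim q}[\nu(Z)] -
#'   E_{Z' \sim p}[\exp(\nu(Z'))] + 1.}
#' Maximized over critics \eqn{\nu}, the supremum equals
#' \eqn{KL(q \| p)} (attained at \eqn{\nu^* = \log(q/p)}); the additive
#' constant 1 normalizes the dual form so the optimum is the KL itself
#' rather than KL \eqn{- 1}, and changes no gradient. The exponent is
#' clamped at 30 for stability.
#'
#' @param q_samples samples from the (aggregated) posterior, \code{n x p}.
#' @param p_samples samples from the prior, \code{m x p}.
#' @param critic a [vie_critic()], or a function \code{z -> value} (used by
#'   tests to plug the analytic optimal critic).
#' @param params optional tape-wrapped critic parameters.
#' @return scalar value of the objective.
#' @export
fenchel_gamma <- function(q_samples, p_samples, critic, params = NULL) {
  stopifnot(nrow(ad_value(q_samples)) > 0, nrow(ad_value(p_samples)) > 0)
  nu <- function(z) {
    if (is.function(critic)) matrix(critic(ad_value(z)), ncol = 1L)
    else critic_value(z, critic, params)
  }
  nq <- nu(q_samples)
  np <- ad_clamp_max(nu(p_samples), FENCHEL_CLAMP)
  out <- ad_add(ad_sub(ad_mean(nq), ad_mean(ad_exp(np))), 1)
  if (is_advar(out)) out else as.numeric(out)
}

#' One gradient-ascent step on the critic
#'
#' Updates the critic parameters \eqn{\omega} by a single Adam ascent step
#' on [fenchel_gamma()], holding both sample sets fixed.
#'
#' @inheritParams fenchel_gamma
#' @param critic a [vie_critic()].
#' @param state Adam state (from [critic_state()] or a previous step).
#' @param lr learning rate.
#' @return list with updated \code{critic}, \code{state}, and the
#'   \code{gamma} value before the update.
#' @export
critic_step <- function(q_samples, p_samples, critic, state = NULL, lr = 1e-4) {
  state <- state %||% critic_state(critic)
  tp <- ad_tape()
  wp <- wrap_params(critic$params, tp)
  gamma <- fenchel_gamma(ad_value(q_samples), ad_value(p_samples), critic, wp)
  ad_backward(gamma)
  up <- adam_step(critic$params, collect_grads(wp), state, lr, maximize = TRUE)
  critic$params <- up$params
  list(critic = critic, state = up$state, gamma = as.numeric(ad_value(gamma)))
}

#' Fresh Adam state for a critic
#' @param critic a [vie_critic()].
#' @export
critic_state <- function(critic) adam_init(critic$params)

#' Train a critic to convergence on two fixed sample sets
#'
#' Convenience wrapper running [critic_step()] repeatedly; used to read off
#' the converged Fenchel KL estimate between two empirical distributions.
#'
#' @inheritParams critic_step
#' @param steps number of ascent steps.
#' @param eval_q,eval_p optional held-out sample sets for the final
#'   estimate (defaults to the training sets).
#' @return list with \code{critic}, \code{estimate} (Gamma on the
#'   evaluation sets), and the \code{trace} of objective values.
#' @export
fenchel_estimate <- function(q_samples, p_samples, critic, steps = 400L,
                             lr = 5e-3, eval_q = NULL, eval_p = NULL) {
  state <- critic_state(critic)
  trace <- numeric(steps)
  for (i in seq_len(steps)) {
    st <- critic_step(q_samples, p_samples, critic, state, lr)
    critic <- st$critic; state <- st$state; trace[i] <- st$gamma
  }
  list(critic = critic,
       estimate = fenchel_gamma(eval_q %||% q_samples,
                                eval_p %||% p_samples, critic),
       trace = trace)
}
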