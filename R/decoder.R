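# Additive monotonic neural network (AMNN) decoder with complementary
# log-log likelihood. The score is
#   H(z; theta) = sum_j alpha_j * int_l^{z_j} h_j(s) ds + gamma,
# with each integrand h_j a one-input network made strictly positive by an
# exponential output activation, so every summand is monotone in z_j and the
# sign of alpha_j sets the effect direction (event stimulator vs blocker).

#' Construct AMNN decoder parameters
#'
#' @param p latent dimension (one integrand network per dimension).
#' @param hidden hidden width of each integrand network.
#' @param lower_end lower integration limit \code{l}; the default \code{-10}
#'   lies beyond the effective support of the latent prior.
#' @param n_grid number of trapezoidal quadrature intervals per integral
#'   (at least 2).
#' @param gamma initial bias; for rare events, initializing near
#'   \code{log(-log(1 - prevalence))} starts the model at the base rate.
#' @param seed integer seed for initialization.
#' @return an object of class \code{amnn_params}.
#' @export
amnn_params <- function(p, hidden = 16L, lower_end = -10, n_grid = 64L,
                        gamma = 0, seed = 1L) {
  stopifnot(p >= 1, n_grid >= 2)
  with_seed(seed, {
    structure(list(
      kind = "amnn", p = as.integer(p),
      lower_end = lower_end, n_grid = as.integer(n_grid),
      integrands = lapply(seq_len(p), function(j)
        init_mlp(c(1L, hidden, 1L))),
      alpha = matrix(stats::rnorm(p, sd = 0.1), 1L, p),
      gamma = matrix(gamma, 1L, 1L),
      cache_env = new.env(parent = emptyenv())
    ), class = "amnn_params")
  })
}

#' Plain MLP decoder (ablation variant)
#'
#' A feed-forward score network under the same complementary log-log link,
#' used for the vanilla-VAE wiring; it is neither additive nor monotone.
#'
#' @inheritParams amnn_params
#' @export
mlp_decoder_params <- function(p, hidden = 32L, gamma = 0, seed = 1L) {
  with_seed(seed, {
    net <- init_mlp(c(p, hidden, 1L))
    net[[length(net)]]$b[1, 1] <- gamma
    structure(list(kind = "mlp", p = as.integer(p), net = net),
              class = "mlp_decoder_params")
  })
}

#' Positive integrand network
#'
#' Evaluates \eqn{h_j(s) = \exp(\mathrm{net}_j(s)) > 0}.
#'
#' @param s numeric vector (or column matrix) of evaluation points.
#' @param theta_j one integrand's network parameters
#'   (\code{params$integrands[[j]]}).
#' @return positive values, same length as \code{s}.
#' @export
amnn_integrand <- function(s, theta_j) {
  sv <- if (is_advar(s)) s else matrix(as.numeric(ad_value(s)), ncol = 1L)
  out <- ad_exp(ad_clamp_max(mlp_forward(sv, theta_j), AMNN_EXP_CLAMP))
  if (is_advar(out)) out else as.numeric(out)
}

# overflow guard on the integrand exponent (matches the compiled kernel)
AMNN_EXP_CLAMP <- 60

#' Signed trapezoidal integral of one integrand
#'
#' Approximates \eqn{\int_l^{z_j} h_j(s)\,ds} on a uniform grid of
#' \code{n_grid} intervals; the grid endpoints follow \code{z_j}, so on the
#' tape gradients flow through both the integrand and the upper limit
#' (\eqn{\partial/\partial z_j} of the integral is \eqn{h_j(z_j)} by the
#' fundamental theorem, up to quadrature error). Negative when
#' \code{z_j < l}.
#'
#' @param z_j upper limit(s); numeric vector or \code{n x 1} (tape) matrix.
#' @param theta_j integrand network parameters.
#' @param l lower limit.
#' @param n_grid number of trapezoidal intervals.
#' @return integral value per row.
#' @export
integrate_dim <- function(z_j, theta_j, l = -10, n_grid = 64L) {
  zc <- if (is_advar(z_j)) z_j else matrix(as.numeric(z_j), ncol = 1L)
  n <- nrow(ad_value(zc))
  G <- as.integer(n_grid)
  frac <- matrix(seq(0, 1, length.out = G + 1L), 1L)
  span <- ad_sub(zc, l)                             # n x 1
  grid <- ad_add(ad_matmul(span, frac), l)          # n x (G+1)
  flat <- ad_reshape(grid, n * (G + 1L), 1L)
  h <- ad_reshape(ad_exp(ad_clamp_max(mlp_forward(flat, theta_j),
                                      AMNN_EXP_CLAMP)), n, G + 1L)
  w <- matrix(c(0.5, rep(1, G - 1L), 0.5), ncol = 1L)
  out <- ad_mul(ad_div(span, G), ad_matmul(h, w))
  if (is_advar(out)) out else as.numeric(out)
}

#' AMNN score
#'
#' \eqn{H(z;\theta) = \sum_j \alpha_j \int_l^{z_j} h_j(s)\,ds + \gamma}.
#' Monotone non-decreasing in \eqn{z_j} where \eqn{\alpha_j > 0} and
#' non-increasing where \eqn{\alpha_j < 0}.
#'
#' @param z latent matrix (rows = observations) or length-\code{p} vector.
#' @param params an [amnn_params()] (or tape-wrapped copy via
#'   \code{wrapped}).
#' @param wrapped optional tape-wrapped parameter list (training path).
#' @return score per row.
#' @export
amnn_forward <- function(z, params, wrapped = NULL) {
  stopifnot(inherits(params, "amnn_params"))
  zv <- ad_value(z)
  if (is.null(dim(zv))) {
    zv <- matrix(zv, nrow = 1L)
    if (!is_advar(z)) z <- zv
  }
  if (ncol(zv) != params$p) stop("latent dimension mismatch: expected ",
                                 params$p, ", got ", ncol(zv))
  w <- wrapped %||% params[c("integrands", "alpha", "gamma")]
  cache <- amnn_cache(params)
  p <- params$p; G <- params$n_grid; G1 <- G + 1L
  hdim <- ncol(ad_value(w$integrands[[1L]][[1L]]$W))
  n <- nrow(zv)

  # all integrand networks evaluated on all grid points in one fused pass;
  # column layout of the wide matrices is grid-point within latent dimension
  # within hidden unit
  span <- ad_sub(z, params$lower_end)                      # n x p
  M <- ad_add(ad_matmul(span, cache$K), params$lower_end)  # n x (p*G1)
  hint <- ad_amnn_hint(M, w$integrands, G1, hdim)          # n x (p*G1)
  integ <- ad_mul(ad_mul(span, 1 / G), ad_matmul(hint, cache$Wtrap))  # n x p
  out <- ad_add(ad_rowsums(ad_mulrow(integ, w$alpha)), w$gamma)
  if (is_advar(out)) out else as.numeric(out)
}

# Custom tape op wrapping the compiled fused integrand kernels: evaluates
# all p positive integrands on all grid points in one pass and routes
# gradients back to the grid matrix and each integrand's parameters.
ad_amnn_hint <- function(M, integrands, G1, hdim) {
  p <- length(integrands)
  W1 <- matrix(vapply(integrands, function(nt)
    as.numeric(ad_value(nt[[1L]]$W)), numeric(hdim)), hdim, p)
  B1 <- matrix(vapply(integrands, function(nt)
    as.numeric(ad_value(nt[[1L]]$b)), numeric(hdim)), hdim, p)
  W2 <- matrix(vapply(integrands, function(nt)
    as.numeric(ad_value(nt[[2L]]$W)), numeric(hdim)), hdim, p)
  B2 <- vapply(integrands, function(nt)
    as.numeric(ad_value(nt[[2L]]$b)), numeric(1L))
  Mv <- ad_value(M)
  fw <- amnn_kernel_fwd(Mv, W1, B1, W2, B2, G1)
  parents <- c(list(M), unlist(lapply(integrands, function(nt)
    list(nt[[1L]]$W, nt[[1L]]$b, nt[[2L]]$W, nt[[2L]]$b)), recursive = FALSE))
  ad_op(fw$hint, parents, function(g) {
    bw <- amnn_kernel_bwd(g, fw$hint, fw$act, Mv, W1, W2, G1)
    grads <- vector("list", 1L + 4L * p)
    grads[[1L]] <- bw$gM
    for (j in seq_len(p)) {
      grads[[4L * (j - 1L) + 2L]] <- matrix(bw$gW1[, j], 1L)   # l1$W is 1 x h
      grads[[4L * (j - 1L) + 3L]] <- matrix(bw$gB1[, j], 1L)
      grads[[4L * (j - 1L) + 4L]] <- matrix(bw$gW2[, j], ncol = 1L)
      grads[[4L * (j - 1L) + 5L]] <- matrix(bw$gB2[j], 1L, 1L)
    }
    grads
  })
}

# constant index/weight matrices for the fused AMNN pass, cached by shape
amnn_cache <- function(params) {
  env <- params$cache_env
  hdim <- ncol(params$integrands[[1L]][[1L]]$W)
  key <- paste(params$p, params$n_grid, hdim, sep = "_")
  if (!is.null(env) && !is.null(env[[key]])) return(env[[key]])
  p <- params$p; G <- params$n_grid; G1 <- G + 1L
  frac <- seq(0, 1, length.out = G1)
  K <- matrix(0, p, p * G1)
  for (j in seq_len(p)) K[j, (j - 1L) * G1 + seq_len(G1)] <- frac
  tw <- c(0.5, rep(1, G - 1L), 0.5)
  Wtrap <- matrix(0, p * G1, p)
  for (j in seq_len(p)) Wtrap[(j - 1L) * G1 + seq_len(G1), j] <- tw
  out <- list(K = K, Wtrap = Wtrap)
  if (!is.null(env)) env[[key]] <- out
  out
}

#' Decoder score for either decoder kind
#' @keywords internal
decoder_score <- function(z, decoder, wrapped = NULL) {
  if (inherits(decoder, "amnn_params")) return(amnn_forward(z, decoder, wrapped))
  zv <- ad_value(z)
  if (is.null(dim(zv)) && !is_advar(z)) z <- matrix(zv, nrow = 1L)
  net <- if (is.null(wrapped)) decoder$net else wrapped$net
  out <- mlp_forward(z, net)
  if (is_advar(out)) out else as.numeric(out)
}

# Exponent clamp for the CLL link: exp(a) overflows well before a = 710, and
# risks are numerically 1 long before a = 30.
CLL_CLAMP <- 30

#' Complementary log-log log-likelihood
#'
#' \eqn{\ell(1, a) = \log(1 - \exp(-e^a))} and \eqn{\ell(0, a) = -e^a},
#' computed with \code{expm1} and with the exponent clamped at 30.
#'
#' @param y binary labels (0/1).
#' @param a scores, recycled against \code{y}.
#' @return log-likelihood per observation.
#' @export
cll_log_lik <- function(y, a) {
  av <- ad_value(a)
  yv <- as.numeric(y)
  if (!all(yv %in% c(0, 1))) stop("labels must be binary 0/1")
  ea <- exp(pmin(av, CLL_CLAMP))
  v1 <- log(pmax(-expm1(-ea), 1e-300))
  val <- ifelse(yv == 1, v1, -ea)
  if (!is_advar(a)) return(as.numeric(val))
  # d/da: y=1 -> e^a / (e^{e^a} - 1); y=0 -> -e^a; zero where clamped
  dd <- ifelse(yv == 1, ea / pmax(expm1(ea), 1e-300), -ea) * (av < CLL_CLAMP)
  dim(val) <- dim(av); dim(dd) <- dim(av)
  ad_op(val, list(a), function(g) list(g * dd))
}

#' Event probability from a score
#'
#' Inverse complementary log-log link applied to the decoder score:
#' \eqn{P(y=1|z) = 1 - \exp(-e^{H(z;\theta)})}.
#'
#' @param z latent matrix or vector.
#' @param params decoder parameters ([amnn_params()] or
#'   [mlp_decoder_params()]).
#' @return probabilities in \code{(0, 1)}.
#' @export
predicted_risk <- function(z, params) {
  a <- ad_value(decoder_score(z, params))
  cll_inverse(a)
}

cll_inverse <- function(a) -expm1(-exp(pmin(a, CLL_CLAMP)))
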