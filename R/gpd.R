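# Generalized Pareto tail and the Gaussian/GPD mixture latent prior.

# |xi| below this uses the exponential (xi = 0) branch everywhere.
XI_TOL <- 1e-6

#' Generalized Pareto distribution function
#'
#' CDF of the GPD for exceedances above a threshold \code{u}:
#' \deqn{G_{\xi,\sigma,u}(x) = 1 - [1 + \xi (x-u)/\sigma]^{-1/\xi}} for
#' \eqn{\xi \neq 0} and \eqn{1 - \exp[-(x-u)/\sigma]} for \eqn{\xi = 0}.
#' Shapes with \eqn{|\xi|} below \code{1e-6} are evaluated on the exponential
#' branch. For \eqn{\xi < 0} the support is bounded at \eqn{u - \sigma/\xi};
#' points beyond it return 1. Points below \code{u} return 0.
#'
#' @param x numeric vector of evaluation points.
#' @param xi shape parameter (real; \eqn{\xi > 0} gives a heavy power-law
#'   tail, \eqn{\xi < 0} a bounded tail).
#' @param sigma scale parameter, strictly positive.
#' @param u threshold (location).
#' @return probabilities in \code{[0, 1]}.
#' @export
#' @examples
#' gpd_cdf(1, xi = 0, sigma = 1, u = 0)   # 1 - exp(-1)
#' gpd_cdf(1, xi = 1, sigma = 1, u = 0)   # 0.5
gpd_cdf <- function(x, xi, sigma, u = 0) {
  check_gpd(xi, sigma)
  e <- x - u
  if (abs(xi) < XI_TOL) {
    p <- -expm1(-e / sigma)
  } else {
    arg <- 1 + xi * e / sigma
    p <- ifelse(arg <= 0,
                if (xi < 0) 1 else 0,   # beyond upper endpoint / below u
                -expm1(-log(pmax(arg, 1e-300)) / xi))
  }
  p[e < 0] <- 0
  pmin(pmax(p, 0), 1)
}

#' GPD log-density
#'
#' Log of the density corresponding to [gpd_cdf()]. Points outside the
#' support return \code{-Inf}.
#'
#' @inheritParams gpd_cdf
#' @return log-densities.
#' @export
gpd_log_pdf <- function(x, xi, sigma, u = 0) {
  check_gpd(xi, sigma)
  e <- x - u
  if (abs(xi) < XI_TOL) {
    out <- -log(sigma) - e / sigma
    out[e < 0] <- -Inf
  } else {
    arg <- 1 + xi * e / sigma
    out <- ifelse(e >= 0 & arg > 0,
                  -log(sigma) - (1 / xi + 1) * log(pmax(arg, 1e-300)),
                  -Inf)
  }
  out
}

#' GPD quantile function
#'
#' Inverse of [gpd_cdf()].
#'
#' @param q probabilities in \code{[0, 1)}.
#' @inheritParams gpd_cdf
#' @return quantiles.
#' @export
gpd_quantile <- function(q, xi, sigma, u = 0) {
  check_gpd(xi, sigma)
  stopifnot(all(q >= 0), all(q < 1))
  if (abs(xi) < XI_TOL) u - sigma * log1p(-q)
  else u + sigma * ((1 - q)^(-xi) - 1) / xi
}

check_gpd <- function(xi, sigma) {
  if (any(!is.finite(xi))) stop("GPD shape `xi` must be finite")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("GPD scale `sigma` must be strictly positive")
  invisible(TRUE)
}

#' Translate GPD tail parameters past the Gaussian body
#'
#' The mixture prior is a standard Gaussian truncated at \code{u} with a GPD
#' tail above it. For \eqn{z > u} the mixture CDF
#' \eqn{\Phi(u) + (1-\Phi(u)) G_{\xi,\sigma}(z-u)} can itself be written as a
#' single GPD with translated parameters \eqn{(\tilde\xi, \tilde\sigma,
#' \tilde u)}: \eqn{\tilde\xi = \xi} and, for \eqn{\xi \neq 0},
#' \eqn{\tilde\sigma = \sigma (1-\Phi(u))^{\xi}},
#' \eqn{\tilde u = u - \tilde\sigma ((1-\Phi(u))^{-\xi} - 1)/\xi}; for
#' \eqn{\xi = 0}, \eqn{\tilde\sigma = \sigma} and
#' \eqn{\tilde u = u + \sigma \log(1-\Phi(u))}. The translated form makes the
#' mixture CDF exactly continuous at \code{u}.
#'
#' @inheritParams gpd_cdf
#' @return list with components \code{xi_t}, \code{sigma_t}, \code{u_t}.
#' @export
translate_tail_params <- function(xi, sigma, u) {
  check_gpd(xi, sigma)
  cc <- stats::pnorm(u, lower.tail = FALSE)    # 1 - Phi(u)
  if (abs(xi) < XI_TOL) {
    sigma_t <- sigma
    u_t <- u + sigma * log(cc)
  } else {
    sigma_t <- sigma * cc^xi
    u_t <- u - sigma_t * (cc^(-xi) - 1) / xi
  }
  list(xi_t = xi, sigma_t = sigma_t, u_t = u_t)
}

# --- prior containers --------------------------------------------------------

#' Mixed Gaussian/GPD latent prior
#'
#' Factorized latent prior: each of the \code{p} dimensions is a standard
#' Gaussian below a shared threshold \code{u} and a Generalized Pareto tail
#' above it, continuous at \code{u}. The per-dimension shape \eqn{\xi_j} is
#' unconstrained; the scale is stored as an unconstrained value mapped
#' through softplus, so it stays positive during gradient training.
#'
#' @param p latent dimensionality.
#' @param u shared tail threshold; the default \code{qnorm(0.99)} puts 1\%
#'   of prior mass in the tail of each dimension.
#' @param xi per-dimension shape(s), recycled to length \code{p}.
#' @param sigma per-dimension scale(s), strictly positive, recycled.
#' @return an object of class \code{mixed_gpd_prior}.
#' @seealso [mixture_cdf()], [mixture_sample()], [gaussian_prior()]
#' @export
mixed_gpd_prior <- function(p, u = stats::qnorm(0.99), xi = 0.1, sigma = 1) {
  stopifnot(p >= 1)
  check_gpd(xi, sigma)
  structure(list(
    p = as.integer(p), u = u,
    xi = rep_len(as.numeric(xi), p),
    sigma_raw = rep_len(softplus_inv(as.numeric(sigma)), p)
  ), class = "mixed_gpd_prior")
}

#' Standard Gaussian latent prior (vanilla-VAE ablation)
#'
#' @param p latent dimensionality.
#' @return an object of class \code{gaussian_prior}.
#' @export
gaussian_prior <- function(p) {
  structure(list(p = as.integer(p)), class = "gaussian_prior")
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  y + log(-expm1(-y))
}

prior_sigma <- function(prior) softplus(prior$sigma_raw)

#' Mixture prior CDF
#'
#' \eqn{F(z) = \Phi(z)} for \eqn{z \le u} and the translated-parameter GPD
#' CDF \eqn{G_{\tilde u, \xi, \tilde\sigma}(z)} for \eqn{z > u}.
#'
#' @param z numeric vector of evaluation points.
#' @param prior a [mixed_gpd_prior()].
#' @param dim which latent dimension's parameters to use.
#' @return probabilities.
#' @export
mixture_cdf <- function(z, prior, dim = 1L) {
  stopifnot(inherits(prior, "mixed_gpd_prior"), dim >= 1, dim <= prior$p)
  xi <- prior$xi[dim]; sigma <- prior_sigma(prior)[dim]; u <- prior$u
  tr <- translate_tail_params(xi, sigma, u)
  ifelse(z <= u, stats::pnorm(z),
         gpd_cdf(z, tr$xi_t, tr$sigma_t, tr$u_t))
}

#' Mixture prior log-density
#'
#' Standard normal log-density below the threshold; translated-GPD
#' log-density above it (which equals \eqn{\log(1-\Phi(u))} plus the GPD
#' log-density of the exceedance).
#'
#' @inheritParams mixture_cdf
#' @return log-densities.
#' @export
mixture_log_pdf <- function(z, prior, dim = 1L) {
  stopifnot(inherits(prior, "mixed_gpd_prior"), dim >= 1, dim <= prior$p)
  xi <- prior$xi[dim]; sigma <- prior_sigma(prior)[dim]; u <- prior$u
  tr <- translate_tail_params(xi, sigma, u)
  ifelse(z <= u, stats::dnorm(z, log = TRUE),
         gpd_log_pdf(z, tr$xi_t, tr$sigma_t, tr$u_t))
}

#' Mixture prior quantile function
#'
#' @param q probabilities in \code{(0, 1)}.
#' @inheritParams mixture_cdf
#' @export
mixture_quantile <- function(q, prior, dim = 1L) {
  stopifnot(inherits(prior, "mixed_gpd_prior"), dim >= 1, dim <= prior$p)
  stopifnot(all(q > 0), all(q < 1))
  xi <- prior$xi[dim]; sigma <- prior_sigma(prior)[dim]; u <- prior$u
  pu <- stats::pnorm(u)
  out <- numeric(length(q))
  body <- q <= pu
  out[body] <- stats::qnorm(q[body])
  if (any(!body)) {
    # conditional-exceedance quantile: V = (1-q)/(1-Phi(u)) in (0,1)
    v <- (1 - q[!body]) / (1 - pu)
    out[!body] <- if (abs(xi) < XI_TOL) u - sigma * log(v)
                  else u + sigma * (v^(-xi) - 1) / xi
  }
  out
}

#' Sample from the mixture prior
#'
#' Inverse-CDF sampling: closed-form quantiles exist on both branches.
#'
#' @param n number of draws.
#' @param prior a [mixed_gpd_prior()] or [gaussian_prior()].
#' @param seed optional integer; when given, sampling is reproducible and
#'   the caller's RNG state is untouched.
#' @return an \code{n x p} matrix of latent draws.
#' @export
mixture_sample <- function(n, prior, seed = NULL) {
  stopifnot(n >= 1)
  draw <- function() {
    if (inherits(prior, "gaussian_prior"))
      return(matrix(stats::rnorm(n * prior$p), n, prior$p))
    u01 <- matrix(stats::runif(n * prior$p), n, prior$p)
    vapply(seq_len(prior$p),
           function(j) mixture_quantile(u01[, j], prior, j),
           numeric(n)) |> matrix(n, prior$p)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Per-row total log prior density of an n x p latent matrix.
#' Total log prior density
#'
#' Sums the per-dimension log-density over latent dimensions for each row.
#'
#' @param z an \code{n x p} matrix of latent points.
#' @param prior a [mixed_gpd_prior()] or [gaussian_prior()].
#' @return length-\code{n} vector.
#' @export
prior_log_pdf <- function(z, prior) UseMethod("prior_log_pdf", prior)

#' @export
prior_log_pdf.gaussian_prior <- function(z, prior) {
  z <- as_matrix_p(z, prior$p)
  rowSums(stats::dnorm(z, log = TRUE))
}

#' @export
prior_log_pdf.mixed_gpd_prior <- function(z, prior) {
  z <- as_matrix_p(z, prior$p)
  out <- numeric(nrow(z))
  for (j in seq_len(prior$p)) out <- out + mixture_log_pdf(z[, j], prior, j)
  out
}

as_matrix_p <- function(z, p) {
  if (is.null(dim(z))) z <- matrix(z, ncol = p)
  stopifnot(ncol(z) == p)
  z
}

#' Peaks-over-threshold GPD fit
#'
#' Maximum-likelihood fit of \eqn{(\xi, \sigma)} to the exceedances of
#' \code{x} above \code{u}. Used to verify tail recovery from samples.
#'
#' @param x numeric sample.
#' @param u threshold; observations \code{<= u} are discarded.
#' @return list with \code{xi}, \code{sigma}, \code{n_exc}, \code{loglik}.
#' @export
fit_gpd_pot <- function(x, u) {
  e <- x[x > u] - u
  if (length(e) < 10) stop("too few exceedances above `u` to fit a GPD")
  nll <- function(par) {
    xi <- par[1]; sigma <- exp(par[2])
    arg <- 1 + xi * e / sigma
    if (any(arg <= 0)) return(1e10)
    if (abs(xi) < XI_TOL) sum(log(sigma) + e / sigma)
    else sum(log(sigma) + (1 / xi + 1) * log(arg))
  }
  fit <- stats::optim(c(0.1, log(mean(e))), nll, method = "Nelder-Mead")
  list(xi = fit$par[1], sigma = exp(fit$par[2]),
       n_exc = length(e), loglik = -fit$value)
}

# --- tape versions (training path) -------------------------------------------

# Broadcast a 1 x p parameter row against n rows.
rep_rows <- function(param, n) ad_matmul(matrix(1, n, 1), param)

# Log-density of the mixture prior on the tape. `z` is an n x p node (or
# matrix), `xi` and `sigma_raw` are 1 x p nodes. Written with per-element
# branch masks so gradients flow into z and into the tail parameters.
mixture_log_pdf_ad <- function(z, xi, sigma_raw, u) {
  zv <- ad_value(z)
  n <- nrow(zv)
  log_c <- stats::pnorm(u, lower.tail = FALSE, log.p = TRUE)
  sigma <- rep_rows(ad_softplus(sigma_raw), n)
  xiw <- rep_rows(xi, n)
  xv <- ad_value(xiw)

  tail_mask <- (zv > u) * 1
  exc <- ad_sub(z, u)
  # xi != 0 branch (safe xi where |xi| < tol, masked out below)
  xi_safe <- ad_select((abs(xv) >= XI_TOL) * 1, xiw, matrix(1, n, ncol(zv)))
  arg <- ad_add(1, ad_div(ad_mul(xi_safe, exc), sigma))
  argv <- ad_value(arg)
  arg_ok <- ad_select((argv > 1e-10) * 1, arg, matrix(1e-10, n, ncol(zv)))
  lp_tail_nz <- ad_sub(ad_neg(ad_log(sigma)),
                       ad_mul(ad_add(ad_div(1, xi_safe), 1), ad_log(arg_ok)))
  lp_tail_z <- ad_sub(ad_neg(ad_log(sigma)), ad_div(exc, sigma))
  lp_tail <- ad_add(log_c,
                    ad_select((abs(xv) >= XI_TOL) * 1, lp_tail_nz, lp_tail_z))
  lp_body <- ad_sub(ad_mul(-0.5, ad_mul(z, z)), 0.5 * log(2 * pi))
  ad_select(tail_mask, lp_tail, lp_body)       # n x p node
}

# Reparameterized prior sampling on the tape: z = Q(U; xi, sigma) for fixed
# uniforms U, so the Fenchel penalty's prior expectation passes gradients to
# the tail parameters. Body draws are constants (the Gaussian body has no
# learnable parameters).
mixture_rsample_ad <- function(u01, xi, sigma_raw, u) {
  n <- nrow(u01); p <- ncol(u01)
  pu <- stats::pnorm(u)
  sigma <- rep_rows(ad_softplus(sigma_raw), n)
  xiw <- rep_rows(xi, n)
  xv <- ad_value(xiw)
  body_mask <- (u01 <= pu) * 1
  zbody <- stats::qnorm(pmin(u01, pu))
  v <- pmax((1 - u01) / (1 - pu), 1e-12)       # conditional survival, tail only
  v[u01 <= pu] <- 1                             # neutral value on body entries
  xi_safe <- ad_select((abs(xv) >= XI_TOL) * 1, xiw, matrix(1, n, p))
  # v^{-xi} = exp(-xi * log v)
  vpow <- ad_exp(ad_mul(ad_neg(xi_safe), log(v)))
  t_nz <- ad_div(ad_sub(vpow, 1), xi_safe)
  t_z <- -log(v)
  tt <- ad_select((abs(xv) >= XI_TOL) * 1, t_nz, t_z)
  ztail <- ad_add(u, ad_mul(sigma, tt))
  ad_select(body_mask, zbody, ztail)
}
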