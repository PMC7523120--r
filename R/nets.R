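# Dense-network building blocks shared by the encoder, flow conditioners,
# monotonic integrands and the critic: initialization, forward passes that
# work both on plain matrices and on the autodiff tape, masked (MADE-style)
# autoregressive layers, and an Adam optimizer over nested parameter lists.

init_dense <- function(fan_in, fan_out, scale = NULL) {
  scale <- scale %||% sqrt(2 / (fan_in + fan_out))
  list(W = matrix(stats::rnorm(fan_in * fan_out, sd = scale), fan_in, fan_out),
       b = matrix(0, 1, fan_out))
}

# Plain MLP parameters: sizes = c(in, h1, ..., out).
init_mlp <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L),
         function(i) init_dense(sizes[i], sizes[i + 1L]))
}

# Forward through an MLP; tanh on hidden layers, linear output.
mlp_forward <- function(x, layers) {
  n <- length(layers)
  h <- x
  for (i in seq_len(n)) {
    h <- ad_addbias(ad_matmul(h, layers[[i]]$W), layers[[i]]$b)
    if (i < n) h <- ad_tanh(h)
  }
  h
}

# --- MADE-style autoregressive masks ----------------------------------------
#
# The flow conditioner must have strictly upper-triangular Jacobians with
# respect to z: output j may depend only on z_k with k > j (and freely on the
# context). This is the standard MADE construction with the dimension order
# reversed; ordering is fixed across steps.

made_masks <- function(p, ctx, h1, h2) {
  o <- p:1                                        # degree of z_k is p - k + 1
  dm <- function(n_hidden) ((seq_len(n_hidden) - 1L) %% max(p - 1L, 1L)) + 1L
  d1 <- dm(h1); d2 <- dm(h2)
  M1 <- rbind(outer(o, d1, `<=`) * 1,             # z rows
              matrix(1, ctx, h1))                 # context rows: unmasked
  M2 <- outer(d1, d2, `<=`) * 1
  Mout <- outer(d2, o, `<`) * 1                   # strict: no self-dependence
  list(M1 = M1, M2 = M2, Mout = cbind(Mout, Mout))  # two p-wide heads
}

init_conditioner <- function(p, ctx, hidden) {
  list(l1 = init_dense(p + ctx, hidden),
       l2 = init_dense(hidden, hidden),
       out = init_dense(hidden, 2L * p))
}

# Masked conditioner forward: returns list(mu, s_raw), each n x p.
conditioner_forward <- function(z, context, cp, masks) {
  inp <- if (is_advar(z) || is_advar(context)) {
    # context never carries gradient w.r.t. z ordering; cbind on values with
    # column scatter keeps both gradient paths
    ad_cbind2(z, context)
  } else cbind(z, context)
  h1 <- ad_tanh(ad_addbias(ad_matmul(inp, ad_mul(cp$l1$W, masks$M1)), cp$l1$b))
  h2 <- ad_tanh(ad_addbias(ad_matmul(h1, ad_mul(cp$l2$W, masks$M2)), cp$l2$b))
  out <- ad_addbias(ad_matmul(h2, ad_mul(cp$out$W, masks$Mout)), cp$out$b)
  p <- ncol(ad_value(out)) / 2L
  list(mu = ad_cols(out, 1:p), s_raw = ad_cols(out, (p + 1L):(2L * p)))
}

# column-bind two (possibly tape) matrices
ad_cbind2 <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ka <- ncol(av)
  ad_op(cbind(av, bv), list(a, b), function(g) {
    list(g[, seq_len(ka), drop = FALSE],
         g[, -seq_len(ka), drop = FALSE])
  })
}

# --- nested parameter-list utilities -----------------------------------------

param_map <- function(f, x) {
  if (is.matrix(x) || is_advar(x)) f(x)
  else lapply(x, function(e) param_map(f, e))
}

param_map2 <- function(f, x, y) {
  if (is.matrix(x) || is_advar(x)) f(x, y)
  else Map(function(a, b) param_map2(f, a, b), x, y)
}

wrap_params <- function(params, tape) param_map(function(m) ad_leaf(m, tape), params)
unwrap_params <- function(wrapped) param_map(ad_value, wrapped)
collect_grads <- function(wrapped) param_map(ad_grad, wrapped)

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = param_map(function(x) array(0, dim(x)), params),
       v = param_map(function(x) array(0, dim(x)), params),
       t = 0L)
}

# One ascent (maximize = TRUE) or descent step; returns list(params, state).
adam_step <- function(params, grads, state, lr, maximize = TRUE,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  sgn <- if (maximize) 1 else -1
  state$m <- param_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- param_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  params <- param_map2(function(p, u) p + sgn * lr * u, params, upd)
  list(params = params, state = state)
}
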