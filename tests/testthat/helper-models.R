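# Shared fixtures: tiny models and a central-finite-difference gradient
# checker used across the unit tests. Everything is built in code at test
# time under fixed seeds.

fd_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulated classification problem shared by training tests
tiny_sim <- function(n = 1200, d = 6, rate = 0.1, seed = 42) {
  ds <- simulate_dataset(sim_config(n = n, d = d, g_type = "linear",
                                    target_event_rate = rate, seed = seed))
  sp <- split_dataset(ds, seed = seed + 1)
  list(ds = ds, sp = sp)
}

# a fast training configuration for smoke-level fitting; ... overrides
tiny_config <- function(variant = "vie", seed = 1, ...) {
  args <- list(variant = variant, latent_dim = 4L, flow_depth = 1L,
               enc_hidden = 8L, context_dim = 4L, cond_hidden = 8L,
               integrand_hidden = 4L, critic_hidden = 16L, dec_hidden = 8L,
               n_grid = 16L, batch_size = 128L, max_epochs = 3L,
               patience = 3L, val_s_eval = 2L, s_eval = 5L, seed = seed)
  do.call(vie_config, utils::modifyList(args, list(...)))
}
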