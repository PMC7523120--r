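# vie — Variational Inference for Extremals

Rare-event (heavily imbalanced) binary classification for biostatistics and
epidemiological modeling. When the outcome of interest — death, ICU
transfer, disease onset — occurs in only 1–5% of subjects, likelihood-driven
classifiers are dominated by the majority class. `vie` recasts the problem
as learning an *extreme latent representation*: events are assumed to be
driven by extreme values of latent factors, and the model puts its capacity
exactly where the rare signal lives.

The model combines four components:

- **Mixed Gaussian/GPD latent prior** — each latent dimension is a standard
  Gaussian below a threshold `u = qnorm(0.99)` and a Generalized Pareto
  tail above it, continuous at `u`:
  `F(z) = Φ(z)` for `z ≤ u`, `F(z) = Φ(u) + (1−Φ(u))·G_{ξ,σ}(z−u)` for
  `z > u`, with learnable per-dimension tail shape `ξ` and scale `σ`.
  Extreme-value theory says two parameters per tail are enough — which is
  all the data a 1% event rate can support.
- **Inverse autoregressive flow posterior** `q(z|x)` — affine
  autoregressive steps `z_t = μ_t + σ_t ⊙ z_{t−1}` over a Gaussian base,
  with an exact log-density for unbiased KL estimation.
- **Additive monotonic decoder** —
  `H(z) = Σ_j α_j ∫_l^{z_j} h_j(s) ds + γ` with strictly positive neural
  integrands `h_j`, under a complementary log-log link
  `P(y=1|z) = 1 − exp(−e^H)`. Additive, so latent effects are disentangled;
  monotone per dimension, so `α_j > 0` reads as an event stimulator and
  `α_j < 0` as a blocker.
- **Fenchel mini-max prior matching** — the aggregated posterior is pulled
  toward the prior through the dual KL estimator
  `Γ = E_q[ν(Z)] − E_p[exp(ν(Z'))] + 1`, maximized over a critic network
  `ν`, yielding the training program `max_{θ,φ,ψ} min_ν Ψ_β − λΓ`.

A Cox proportional-hazards Weibull simulator
(`T = {−log U / (λ e^{g(x)})}^{1/ν}`, labels `y = 1(T < t₀)` with the
cut-off `t₀` tuned to any target event rate) plus AUC/AUPRC evaluation with
stratified bootstrap confidence intervals make every component testable
without access to clinical data.

## Worked example

Simulate a 1%-prevalence cohort, train the full model, and evaluate:

```r
library(vie)

ds <- simulate_dataset(sim_config(n = 10000, d = 10, g_type = "linear",
                                  target_event_rate = 0.01, seed = 303))
sp <- split_dataset(ds, seed = 404)          # 6:2:2 train/val/test

cfg <- vie_config(variant = "vie", lr = 1e-2, lr_critic = 1e-3,
                  batch_size = 256, max_epochs = 15, patience = 15,
                  enc_hidden = 16, cond_hidden = 16, integrand_hidden = 8,
                  critic_hidden = 32, n_grid = 32, s_eval = 40, seed = 1)
fit <- vie_train(ds$X[sp$train, ], ds$y[sp$train],
                 ds$X[sp$val, ], ds$y[sp$val], cfg)

risk <- predict_risk(fit, ds$X[sp$test, ], seed = 2)
eval_report(risk, ds$y[sp$test], n_boot = 1000, seed = 3)
#> AUC   0.645  [0.508, 0.764]
#> AUPRC 0.018  [0.012, 0.042]  (1000 bootstrap resamples, 95%)
auc(ds$oracle_risk[sp$test], ds$y[sp$test])
#> [1] 0.7289394
```

A test AUC of 0.645 against an oracle ceiling of 0.729, earned from just 60
training positives; the wide intervals are what 20 test-set positives look
like, and are exactly why the package reports bootstrap confidence
intervals rather than point estimates. (At a 5% event rate the same
configuration comes within a few AUC points of the oracle — see the
methods vignette.) `fit$prior$xi` holds the fitted per-dimension tail
shapes; positive values mark latent dimensions that learned
heavier-than-Gaussian tails.

The five ablation wirings (`vae`, `vae_gpd`, `iaf_gpd`, `fenchel_gpd`,
`vie`) are one config field apart; `ablation_harness()` repeats
simulate/train/evaluate across seeds and tabulates mean ± sd per variant
next to the oracle.

A thin command-line front-end is installed as `vie`
(`vie train / simulate / evaluate / ablate`); see `exec/vie` for usage.

## Package layout

- `R/gpd.R` — GPD and mixture-prior distribution functions, tail
  translation, sampling, POT fitting
- `R/encoder.R` — flow posterior and implicit sampler
- `R/decoder.R` — monotonic decoder and cloglog likelihood
- `R/divergence.R` — Monte-Carlo, closed-form, and Fenchel KL estimators
- `R/training.R` — objective, mini-max loop, prediction, checkpoints
- `R/simulate.R`, `R/evaluate.R` — survival simulator; metrics and harness
- `R/autodiff.R`, `R/nets.R`, `src/` — reverse-mode tape, network blocks,
  compiled decoder kernels
- `vignettes/vie-methods.Rmd` — the model, its assumptions, and every
  numerical choice, in detail
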