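# Threshold-free evaluation for rare-event classifiers: AUC and AUPRC with
# stratified bootstrap confidence intervals, and the repeated-simulation
# harness for ablation comparisons.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimate: the probability that a random
#' positive is scored above a random negative, with ties counting one half.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary labels (0/1) of the same length.
#' @return AUC in \code{[0, 1]}.
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
auc <- function(scores, labels) {
  labels <- check_labels(labels, scores)
  if (length(unique(labels)) < 2L)
    stop("labels must contain at least one 0 and one 1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)                       # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise area: precision-recall points are taken at every distinct
#' score threshold (equal scores form one block) and the area is
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} with no interpolation above the steps.
#' Equals average precision on tie-free scores; a constant ranker scores
#' the prevalence, a perfect ranker 1.
#'
#' @inheritParams auc
#' @return AUPRC in \code{[0, 1]}.
#' @export
auprc <- function(scores, labels) {
  labels <- check_labels(labels, scores)
  if (sum(labels == 1) == 0L) stop("labels must contain at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # collapse tied scores into threshold blocks
  idx <- cumsum(rle(s)$lengths)           # last index of each block
  tp <- cumsum(y)[idx]
  npred <- idx
  prec <- tp / npred
  rec <- tp / sum(labels == 1)
  sum(diff(c(0, rec)) * prec)
}

check_labels <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (any(!is.finite(scores))) stop("scores must be finite")
  labels
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples positives and negatives separately (both classes are present
#' in every resample) and returns the percentile interval of the metric.
#'
#' @inheritParams auc
#' @param metric a function \code{(scores, labels) -> scalar}, e.g. [auc()].
#' @param n_boot number of resamples (at least 100).
#' @param seed integer seed.
#' @param level confidence level.
#' @return list with \code{lo}, \code{hi}, \code{point}, \code{boot}
#'   (the resampled values).
#' @export
bootstrap_ci <- function(scores, labels, metric = auc, n_boot = 1000L,
                         seed = 1L, level = 0.95) {
  labels <- check_labels(labels, scores)
  stopifnot(n_boot >= 100)
  ipos <- which(labels == 1); ineg <- which(labels == 0)
  point <- metric(scores, labels)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- c(sample(ipos, length(ipos), replace = TRUE),
           sample(ineg, length(ineg), replace = TRUE))
    metric(scores[i], labels[i])
  }, numeric(1)))
  qs <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(lo = qs[1], hi = qs[2], point = point, boot = boot)
}

#' Evaluation report: AUC and AUPRC with bootstrap intervals
#'
#' @inheritParams bootstrap_ci
#' @return object of class \code{eval_report}: \code{auc}, \code{auprc},
#'   \code{ci_auc}, \code{ci_auprc}, \code{n_boot}.
#' @export
eval_report <- function(scores, labels, n_boot = 1000L, seed = 1L,
                        level = 0.95) {
  ca <- bootstrap_ci(scores, labels, auc, n_boot, seed, level)
  cp <- bootstrap_ci(scores, labels, auprc, n_boot, derive_seed(seed, 1), level)
  structure(list(auc = ca$point, auprc = cp$point,
                 ci_auc = c(ca$lo, ca$hi), ci_auprc = c(cp$lo, cp$hi),
                 n_boot = n_boot, level = level),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AUC   %.3f  [%.3f, %.3f]\n", x$auc, x$ci_auc[1], x$ci_auc[2]))
  cat(sprintf("AUPRC %.3f  [%.3f, %.3f]  (%d bootstrap resamples, %g%%)\n",
              x$auprc, x$ci_auprc[1], x$ci_auprc[2], x$n_boot, 100 * x$level))
  invisible(x)
}

#' Repeated-simulation ablation harness
#'
#' For each repeat: draw a fresh simulated dataset (seed + repeat index),
#' split 6:2:2, train each requested model variant, and evaluate on the
#' test fold; the closed-form oracle is always included. Returns the
#' mean/sd summary table across repeats.
#'
#' @param sim_config a [sim_config()].
#' @param variants character vector of model variants (see [vie_config()]);
#'   may be empty for an oracle-only run.
#' @param n_repeats number of simulation repeats (at least 2).
#' @param seed master seed.
#' @param train_config a [vie_config()] whose variant field is overridden
#'   per run; controls budgets (epochs, sizes) for all variants.
#' @return list with \code{summary} (data frame: variant, mean/sd of AUC
#'   and AUPRC) and \code{per_replicate} (long data frame of all scores).
#' @export
ablation_harness <- function(sim_config, variants = c("vae", "vie"),
                             n_repeats = 10L, seed = 1L,
                             train_config = vie_config()) {
  stopifnot(n_repeats >= 2)
  rows <- list()
  for (r in seq_len(n_repeats)) {
    sc <- sim_config
    sc$seed <- derive_seed(seed, r)
    ds <- simulate_dataset(sc)
    sp <- split_dataset(ds, seed = derive_seed(seed, 1000 + r))
    rows[[length(rows) + 1L]] <- data.frame(
      repeat_id = r, variant = "oracle",
      auc = auc(ds$oracle_risk[sp$test], ds$y[sp$test]),
      auprc = auprc(ds$oracle_risk[sp$test], ds$y[sp$test]))
    for (v in variants) {
      cfg <- train_config
      cfg$variant <- v
      cfg$seed <- derive_seed(seed, 2000 + r)
      fit <- vie_train(ds$X[sp$train, , drop = FALSE], ds$y[sp$train],
                       ds$X[sp$val, , drop = FALSE], ds$y[sp$val], cfg)
      risk <- predict_risk(fit, ds$X[sp$test, , drop = FALSE],
                           seed = derive_seed(seed, 3000 + r))
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, variant = v,
        auc = auc(risk, ds$y[sp$test]),
        auprc = auprc(risk, ds$y[sp$test]))
    }
  }
  per <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per, per$variant), function(dd)
    data.frame(variant = dd$variant[1],
               auc_mean = mean(dd$auc), auc_sd = stats::sd(dd$auc),
               auprc_mean = mean(dd$auprc), auprc_sd = stats::sd(dd$auprc))))
  rownames(agg) <- NULL
  list(summary = agg[order(match(agg$variant, c(variants, "oracle"))), ],
       per_replicate = per)
}
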