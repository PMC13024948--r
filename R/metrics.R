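#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve computed as the Mann-Whitney U statistic with
#' ties averaged: the probability that a randomly chosen positive case is
#' scored above a randomly chosen negative one.
#'
#' @param preds Numeric scores or probabilities.
#' @param labels Binary 0/1 labels (both classes must be present).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(preds, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires both classes", call. = FALSE)
  r <- rank(preds, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared error of predicted probabilities against binary outcomes.
#'
#' @inheritParams auc_score
#' @return Brier score in [0, 1]; lower is better.
#' @export
brier_score <- function(preds, labels) {
  mean((preds - as.numeric(labels))^2)
}

#' Percentile bootstrap intervals for AUC and Brier score
#'
#' Non-parametric bootstrap of the held-out (prediction, label) pairs.
#' Resamples containing a single outcome class (where AUC is undefined) are
#' redrawn, up to a cap of 1000 attempts per resample.
#'
#' @inheritParams auc_score
#' @param B Number of bootstrap resamples.
#' @param seed Integer RNG seed.
#' @param level Interval level (default 0.95).
#' @return A list with elements `auc_ci`, `brier_ci` (length-2 vectors),
#'   and the bootstrap replicate matrix in `replicates`.
#' @export
bootstrap_ci <- function(preds, labels, B = 200, seed = 1, level = 0.95) {
  stopifnot(length(preds) == length(labels))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- length(preds)
  reps <- matrix(NA_real_, B, 2L, dimnames = list(NULL, c("auc", "brier")))
  for (b in seq_len(B)) {
    for (attempt in seq_len(1000L)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
      if (attempt == 1000L)
        stop("could not draw a two-class bootstrap resample", call. = FALSE)
    }
    reps[b, "auc"] <- auc_score(preds[idx], labels[idx])
    reps[b, "brier"] <- brier_score(preds[idx], labels[idx])
  }
  a <- (1 - level) / 2
  list(auc_ci = unname(stats::quantile(reps[, "auc"], c(a, 1 - a))),
       brier_ci = unname(stats::quantile(reps[, "brier"], c(a, 1 - a))),
       replicates = reps)
}

#' Calibration curve with bootstrap confidence intervals
#'
#' Groups predicted probabilities into equally spaced bins on [0, 1] and
#' compares the mean prediction in each bin with the observed event
#' frequency. Uncertainty in the observed frequencies is quantified by
#' non-parametric bootstrap of the (prediction, label) pairs. Empty bins are
#' flagged (`n = 0`, `NA` frequencies), never fabricated.
#'
#' @inheritParams bootstrap_ci
#' @param n_bins Number of equal-width probability bins (>= 2; default 10).
#' @return A data.frame with one row per bin: bin midpoint, count, mean
#'   predicted probability, observed frequency and bootstrap CI bounds.
#' @export
calibration_curve <- function(preds, labels, n_bins = 10, B = 200, seed = 1) {
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- cut(preds, breaks, include.lowest = TRUE, labels = FALSE)
  n <- length(preds)
  obs_boot <- matrix(NA_real_, B, n_bins)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    bi <- bin[idx]; yi <- as.numeric(labels[idx])
    obs_boot[b, ] <- vapply(seq_len(n_bins), function(k) {
      if (any(bi == k)) mean(yi[bi == k]) else NA_real_
    }, numeric(1L))
  }
  out <- data.frame(
    bin_mid = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
    n = as.integer(tabulate(bin, n_bins)),
    mean_pred = vapply(seq_len(n_bins), function(k)
      if (any(bin == k)) mean(preds[bin == k]) else NA_real_, numeric(1L)),
    obs_freq = vapply(seq_len(n_bins), function(k)
      if (any(bin == k)) mean(as.numeric(labels)[bin == k]) else NA_real_,
      numeric(1L)))
  out$ci_lo <- apply(obs_boot, 2L, function(v)
    if (all(is.na(v))) NA_real_ else stats::quantile(v, 0.025, na.rm = TRUE))
  out$ci_hi <- apply(obs_boot, 2L, function(v)
    if (all(is.na(v))) NA_real_ else stats::quantile(v, 0.975, na.rm = TRUE))
  out$empty <- out$n == 0L
  out
}
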