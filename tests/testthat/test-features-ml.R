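avm_cohort <- simulate_cohort("avm", 300, seed = 1)

test_that("feature families contain exactly the intended columns", {
  fB <- build_features(avm_cohort, feature_spec("B", "avm"))
  expect_true(all(c("bed_target_total", "bed_target_mean_fx", "bed_ge_133",
                    "bed_ge_180", "num_fractions", "total_t_min")
                  %in% fB$feature_names))
  expect_false("total_physical_dose_gy" %in% fB$feature_names)
  fA <- build_features(avm_cohort, feature_spec("A", "avm"))
  expect_false(any(grepl("bed", fA$feature_names, ignore.case = TRUE)))
  expect_true(all(c("total_physical_dose_gy", "n_iso_total")
                  %in% fA$feature_names))
  fC <- build_features(avm_cohort, feature_spec("C", "avm"))
  expect_setequal(fC$feature_names,
                  union(fA$feature_names, fB$feature_names))
  expect_false(anyDuplicated(fC$feature_names) > 0)
  expect_equal(nrow(fB$x), 300)
  # threshold indicators encode BED crossings
  expect_identical(fB$x[, "bed_ge_133"],
                   as.double(avm_cohort$bed_total >= 133))
  i150 <- which(avm_cohort$bed_total > 140 & avm_cohort$bed_total < 180)[1]
  expect_identical(unname(fB$x[i150, c("bed_ge_133", "bed_ge_180")]),
                   c(1, 0))
  # one-hot encoding of the categorical covariates
  loc_cols <- grep("^loc_", fB$feature_names, value = TRUE)
  expect_length(loc_cols, 4L)
  expect_true(all(rowSums(fB$x[, loc_cols]) == 1))
})

test_that("feature construction validates its inputs", {
  vs_cohort <- simulate_cohort("vs", 30, seed = 1)
  expect_error(build_features(vs_cohort, feature_spec("B", "avm")),
               "does not match")
  broken <- avm_cohort
  broken$bed_total <- NULL
  expect_error(build_features(broken, feature_spec("B", "avm")),
               "missing column")
  # lean non-AVM layouts
  fB <- build_features(vs_cohort, feature_spec("B", "vs"))
  expect_identical(fB$feature_names, c("volume", "bed_target_total"))
})

test_that("rank AUC is monotone-invariant, tie-averaged and matches pROC", {
  set.seed(42)
  y <- rbinom(200, 1, 0.4)
  p <- plogis(rnorm(200) + y)
  expect_equal(auc_score(p, y), auc_score(qlogis(p), y))
  expect_equal(auc_score(p, y), auc_score(p^3, y))
  expect_equal(auc_score(rep(0.3, 200), y), 0.5)
  expect_equal(auc_score(y, y), 1)
  skip_if_not_installed("pROC")
  expect_equal(auc_score(p, y),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
  # with heavy ties
  pt <- round(p, 1)
  expect_equal(auc_score(pt, y),
               as.numeric(pROC::auc(pROC::roc(y, pt, quiet = TRUE))))
})

test_that("Brier score is minimised by the true conditional probabilities", {
  set.seed(1)
  truth <- runif(5000, 0.1, 0.9)
  y <- rbinom(5000, 1, truth)
  b_true <- brier_score(truth, y)
  for (eps in c(-0.08, 0.08))
    expect_gt(brier_score(pmin(pmax(truth + eps, 0), 1), y), b_true)
})

test_that("classifier evaluation behaves at the null and at separation", {
  feats <- build_features(avm_cohort, feature_spec("B", "avm"))
  null_feats <- feats
  set.seed(99)
  null_feats$y <- sample(feats$y)  # break the feature-label link
  ev_null <- train_eval(null_feats, "gbt", seed = 1, B = 20)
  expect_lt(abs(ev_null$auc - 0.5), 0.2)
  sep <- list(x = cbind(z = c(rnorm(50, -3), rnorm(50, 3))),
              y = rep(0:1, each = 50))
  expect_equal(train_eval(sep, "logistic", seed = 1, B = 10)$auc, 1)
  expect_error(train_eval(list(x = cbind(z = rnorm(10)), y = rep(1L, 10)),
                          "gbt"), "single class")
  expect_error(train_eval(feats, "nonsense"), "arg")
})

test_that("evaluation reports are identical under the same seed", {
  feats <- build_features(avm_cohort, feature_spec("B", "avm"))
  e1 <- train_eval(feats, "gbt", seed = 7, B = 25)
  e2 <- train_eval(feats, "gbt", seed = 7, B = 25)
  expect_identical(e1$auc, e2$auc)
  expect_identical(e1$preds, e2$preds)
  expect_identical(e1$auc_ci, e2$auc_ci)
})

test_that("bootstrap intervals behave in degenerate settings", {
  y <- rep(c(0L, 1L), 20)
  ci <- bootstrap_ci(rep(0.5, 40), y, B = 50, seed = 1)
  expect_equal(ci$brier_ci[1], ci$brier_ci[2])  # constant preds
  one <- bootstrap_ci(runif(40), y, B = 1, seed = 2)
  expect_equal(one$auc_ci[1], one$auc_ci[2])
  expect_lte(ci$auc_ci[1], ci$auc_ci[2])
  expect_lte(ci$brier_ci[1], ci$brier_ci[2])
})

test_that("calibration curves sit on the diagonal for calibrated predictions", {
  set.seed(3)
  truth <- runif(4000)
  y <- rbinom(4000, 1, truth)
  cal <- calibration_curve(truth, y, n_bins = 10, B = 100, seed = 1)
  occ <- !cal$empty
  expect_true(all(abs(cal$obs_freq[occ] - cal$mean_pred[occ]) < 0.08))
  expect_true(all(cal$ci_lo[occ] <= cal$ci_hi[occ]))
  # single occupied bin for constant predictions
  cal2 <- calibration_curve(rep(0.5, 100), rep(0:1, 50), n_bins = 10,
                            B = 20, seed = 1)
  expect_equal(sum(!cal2$empty), 1L)
  expect_equal(cal2$obs_freq[!cal2$empty], 0.5)
  expect_equal(sum(cal2$n), 100L)
  expect_error(calibration_curve(truth, y, n_bins = 1), ">= 2")
})

test_that("cross-validation detects the null and rejects degenerate folds", {
  feats <- build_features(avm_cohort, feature_spec("B", "avm"))
  set.seed(4)
  null_feats <- list(x = feats$x, y = sample(feats$y))
  cv <- crossval_auc(null_feats, k = 5, model = "logistic", seed = 1)
  expect_length(cv$fold_auc, 5L)
  expect_lt(abs(cv$mean_auc - 0.5), 0.15)
  expect_error(crossval_auc(feats, k = nrow(feats$x), model = "logistic"),
               "rarest class")
})

test_that("univariate benchmark ranks time-aware BED above physical dose", {
  uni <- univariate_benchmark(avm_cohort, seed = 1)
  expect_identical(uni$metric, c("physical_dose", "lq_bed", "bedfx"))
  expect_lt(uni$auc[1], uni$auc[2])
  expect_gte(uni$auc[3] + 0.03, uni$auc[2])  # bedfx >= LQ up to split noise
  vs_cohort <- simulate_cohort("vs", 30, seed = 1)
  expect_error(univariate_benchmark(vs_cohort), "AVM")
})

test_that("model families agree and BED features never hurt the AVM model", {
  feats <- build_features(avm_cohort, feature_spec("B", "avm"))
  aucs <- vapply(c("gbt", "logistic", "random_forest"), function(m)
    train_eval(feats, m, seed = 2, B = 10)$auc, numeric(1L))
  # comparable discrimination across model families (bootstrap noise at
  # n_test ~ 75 dominates the small architecture differences)
  expect_lt(max(aucs) - min(aucs), 0.06)
  fA <- train_eval(build_features(avm_cohort, feature_spec("A", "avm")),
                   "gbt", seed = 2, B = 10)
  fC <- train_eval(build_features(avm_cohort, feature_spec("C", "avm")),
                   "gbt", seed = 2, B = 10)
  expect_gt(fC$auc, fA$auc - 0.08)  # adding the true driver never degrades
})

test_that("Shapley attribution isolates the generative signal", {
  feats <- build_features(avm_cohort, feature_spec("C", "avm"))
  # add a pure-noise feature: its attribution should be near zero
  set.seed(5)
  feats$x <- cbind(feats$x, noise = rnorm(nrow(feats$x)))
  feats$feature_names <- colnames(feats$x)
  att <- feature_attribution(feats, seed = 1)
  expect_true(all(att$mean_abs_shap >= 0))
  expect_false(is.unsorted(rev(att$mean_abs_shap)))
  expect_identical(att$feature[1], "bed_target_total")
  expect_lt(att$mean_abs_shap[att$feature == "noise"],
            0.2 * att$mean_abs_shap[1])
  # BM outcomes are driven by volume and BED, not the fraction count
  bm <- simulate_cohort("bm", 250, seed = 1)
  att_bm <- feature_attribution(build_features(bm, feature_spec("C", "bm")),
                                seed = 1)
  expect_true("volume" %in% att_bm$feature[1:2])
})
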