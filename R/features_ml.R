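#' Feature family specification
#'
#' Defines which patient-level feature family to build for a pathology:
#' `"A"` clinical + physical dose/time (no BED-derived column), `"B"`
#' clinical + BED-derived features, `"C"` the combination, or `"U"` a single
#' univariate dose metric. For the AVM cohort family B carries the total
#' BED, the mean per-fraction BED and binary indicators for crossing
#' 133 and 180 Gy_2.47; the other pathologies use the leaner layouts of
#' their cohort definitions (volume, physical dose, fraction count, BED).
#'
#' @param family One of `"A"`, `"B"`, `"C"`, `"U"`.
#' @inheritParams outcome_model_params
#' @param metric For family `"U"`: one of `"physical_dose"`, `"lq_bed"`,
#'   `"bedfx"`.
#' @return An object of class `bedfx_feature_spec`.
#' @export
feature_spec <- function(family = c("A", "B", "C", "U"),
                         pathology = c("avm", "vs", "bm", "men"),
                         metric = c("physical_dose", "lq_bed", "bedfx")) {
  family <- match.arg(family)
  pathology <- match.arg(pathology)
  metric <- match.arg(metric)
  structure(list(family = family, pathology = pathology, metric = metric),
            class = "bedfx_feature_spec")
}

# one-hot encode a character column (full dummy set, stable level order)
.one_hot <- function(x, prefix, levels_) {
  m <- sapply(levels_, function(l) as.integer(x == l))
  colnames(m) <- paste0(prefix, "_", gsub("[^a-z0-9]+", "_", levels_))
  m
}

.avm_bed_thresholds <- c(133, 180)

#' Build a patient-level feature table
#'
#' Aggregates a simulated cohort into the machine-learning feature matrix of
#' the requested family (see [feature_spec()]), with categorical covariates
#' one-hot encoded, plus the binary outcome label vector.
#'
#' @param cohort A [simulate_cohort()] result (pathology must match `spec`).
#' @param spec A [feature_spec()].
#' @return A list with `x` (numeric feature matrix, one row per patient),
#'   `y` (integer labels) and `feature_names`.
#' @export
build_features <- function(cohort, spec) {
  if (!inherits(spec, "bedfx_feature_spec"))
    stop("`spec` must be a feature_spec()", call. = FALSE)
  if (!identical(attr(cohort, "pathology"), spec$pathology))
    stop("cohort pathology does not match the feature spec", call. = FALSE)
  req <- c("volume", "num_fractions", "total_dose_gy", "bed_total", "outcome")
  missing <- setdiff(req, names(cohort))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  if (spec$family == "U") {
    metric <- switch(spec$metric,
      physical_dose = cohort$total_dose_gy,
      lq_bed = lq_bed(cohort$num_fractions, cohort$dose_per_fraction,
                      attr(cohort, "kinetics")$alpha_beta),
      bedfx = cohort$bed_total)
    x <- matrix(metric, ncol = 1L, dimnames = list(NULL, spec$metric))
    return(list(x = x, y = as.integer(cohort$outcome),
                feature_names = spec$metric))
  }

  if (spec$pathology == "avm") {
    clinical <- cbind(
      age = cohort$age,
      sex_m = as.integer(cohort$sex == "m"),
      volume = cohort$volume,
      .one_hot(cohort$location, "loc",
               c("lobar", "deep", "cerebellar", "brainstem")),
      prior_rt = cohort$prior_rt,
      prior_surgery = cohort$prior_surgery)
    dose_block <- cbind(
      total_physical_dose_gy = cohort$total_dose_gy,
      num_fractions = cohort$num_fractions,
      total_t_min = cohort$total_time_min,
      n_iso_total = cohort$n_iso_total)
    thr <- sapply(.avm_bed_thresholds,
                  function(th) as.integer(cohort$bed_total >= th))
    colnames(thr) <- paste0("bed_ge_", .avm_bed_thresholds)
    bed_block <- cbind(
      bed_target_total = cohort$bed_total,
      bed_target_mean_fx = cohort$bed_total / cohort$num_fractions,
      thr,
      num_fractions = cohort$num_fractions,
      total_t_min = cohort$total_time_min)
  } else {
    clinical <- cbind(volume = cohort$volume)
    dose_block <- if (spec$pathology == "vs")
      cbind(total_physical_dose_gy = cohort$total_dose_gy)
    else
      cbind(total_physical_dose_gy = cohort$total_dose_gy,
            num_fractions = cohort$num_fractions)
    bed_block <- cbind(bed_target_total = cohort$bed_total)
  }

  x <- switch(spec$family,
    A = cbind(clinical, dose_block),
    B = cbind(clinical, bed_block),
    C = {
      m <- cbind(clinical, dose_block, bed_block)
      m[, !duplicated(colnames(m)), drop = FALSE]
    })
  storage.mode(x) <- "double"
  rownames(x) <- NULL
  list(x = x, y = as.integer(cohort$outcome), feature_names = colnames(x))
}

# quoted gradient-boosting configuration: 200 trees, depth 3, learning rate
# 0.05, row and column subsampling 0.8
.fit_gbt <- function(x, y, seed) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.05,
                  subsample = 0.8, colsample_bytree = 0.8, nthread = 1,
                  seed = as.integer(seed)),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1), nrounds = 200)
}

.fit_predict <- function(x_train, y_train, x_test, model, seed) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  if (model == "gbt") {
    fit <- .fit_gbt(x_train, y_train, seed)
    list(fit = fit,
         preds = stats::predict(fit, xgboost::xgb.DMatrix(x_test)))
  } else if (model == "logistic") {
    df_train <- data.frame(y = y_train, x_train, check.names = TRUE)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = df_train, family = stats::binomial()))
    preds <- suppressWarnings(stats::predict(
      fit, data.frame(x_test, check.names = TRUE), type = "response"))
    list(fit = fit, preds = as.numeric(preds))
  } else if (model == "random_forest") {
    fit <- randomForest::randomForest(x = x_train, y = factor(y_train))
    list(fit = fit, preds = stats::predict(fit, x_test, type = "prob")[, "1"])
  } else {
    stop("unknown model '", model, "'", call. = FALSE)
  }
}

#' Train and evaluate a classifier on a stratified 75/25 split
#'
#' Splits the feature table 75%/25% stratified on the outcome, fits the
#' requested model family on the training part and evaluates discrimination
#' (rank AUC) and calibration (Brier score) on the held-out quarter, with
#' percentile bootstrap confidence intervals (200 resamples of the test
#' set). The gradient-boosted model uses 200 trees of depth 3, learning rate
#' 0.05, and row/column subsampling 0.8; the logistic and random-forest
#' comparators use library defaults.
#'
#' @param features Output of [build_features()] (or a list with `x` and `y`).
#' @param model One of `"gbt"`, `"logistic"`, `"random_forest"`.
#' @param seed Integer seed controlling the split, the model fit and the
#'   bootstrap.
#' @param train_frac Training fraction (default 0.75).
#' @param B Bootstrap resamples for the confidence intervals.
#' @return An object of class `bedfx_eval`: metrics, intervals, held-out
#'   predictions and the fitted model.
#' @export
train_eval <- function(features, model = c("gbt", "logistic", "random_forest"),
                       seed = 1, train_frac = 0.75, B = 200) {
  model <- match.arg(model)
  x <- features$x; y <- features$y
  if (length(unique(y)) < 2L)
    stop("labels contain a single class; cannot train a classifier",
         call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  train <- .stratified_split(y, train_frac)
  fp <- .fit_predict(x[train, , drop = FALSE], y[train],
                     x[!train, , drop = FALSE], model, seed)
  preds <- fp$preds; y_test <- y[!train]
  ci <- bootstrap_ci(preds, y_test, B = B, seed = seed)
  structure(
    list(model = model, auc = auc_score(preds, y_test),
         brier = brier_score(preds, y_test),
         auc_ci = ci$auc_ci, brier_ci = ci$brier_ci,
         n_test = length(y_test), n_train = sum(train), seed = seed,
         preds = preds, labels = y_test, fit = fp$fit,
         feature_names = colnames(x), train_index = which(train)),
    class = "bedfx_eval")
}

#' @export
print.bedfx_eval <- function(x, ...) {
  cat(sprintf("%s classifier: held-out AUC %.3f (95%% CI %.3f-%.3f), Brier %.3f (%.3f-%.3f), n_test = %d\n",
              x$model, x$auc, x$auc_ci[1L], x$auc_ci[2L],
              x$brier, x$brier_ci[1L], x$brier_ci[2L], x$n_test))
  invisible(x)
}

#' Stratified k-fold cross-validated AUC
#'
#' @inheritParams train_eval
#' @param k Number of folds (default 5). Each fold must retain both classes.
#' @return A list with per-fold AUCs, their mean and standard deviation.
#' @export
crossval_auc <- function(features, k = 5, model = "gbt", seed = 1) {
  x <- features$x; y <- features$y
  if (k > min(table(y)))
    stop("`k` exceeds the size of the rarest class; folds would be ",
         "single-class", call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  fold <- .stratified_folds(y, k)
  aucs <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2L)
      stop("fold ", f, " is single-class", call. = FALSE)
    fp <- .fit_predict(x[tr, , drop = FALSE], y[tr],
                       x[!tr, , drop = FALSE], model, seed + f)
    auc_score(fp$preds, y[!tr])
  }, numeric(1L))
  list(fold_auc = aucs, mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
       k = k, model = model, seed = seed)
}

#' Univariate dose-metric benchmark
#'
#' Compares three univariate predictors of the AVM obliteration outcome on
#' one identical stratified 75/25 split: total physical prescription dose,
#' the classical acute LQ BED, and the fraction-resolved biexponential BED.
#' Each metric enters a logistic regression as a single standardized
#' predictor.
#'
#' @param cohort An AVM [simulate_cohort()] result.
#' @param seed Integer seed (split shared by all three metrics).
#' @return A data.frame with one row per metric: AUC and Brier score on the
#'   common held-out set.
#' @export
univariate_benchmark <- function(cohort, seed = 1) {
  if (!identical(attr(cohort, "pathology"), "avm"))
    stop("the univariate benchmark is defined for the AVM cohort",
         call. = FALSE)
  y <- as.integer(cohort$outcome)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  train <- .stratified_split(y, 0.75)
  metrics <- c("physical_dose", "lq_bed", "bedfx")
  res <- lapply(metrics, function(m) {
    f <- build_features(cohort, feature_spec("U", "avm", m))
    mu <- mean(f$x[train, 1L]); sdv <- stats::sd(f$x[train, 1L])
    z <- if (sdv > 0) (f$x[, 1L] - mu) / sdv else f$x[, 1L] * 0
    df <- data.frame(y = y, z = z)
    fit <- suppressWarnings(stats::glm(y ~ z, data = df[train, ],
                                       family = stats::binomial()))
    preds <- as.numeric(stats::predict(fit, df[!train, ], type = "response"))
    data.frame(metric = m, auc = auc_score(preds, y[!train]),
               brier = brier_score(preds, y[!train]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "n_test") <- sum(!train)
  out
}

#' Shapley-value feature attribution for tree ensembles
#'
#' Refits the gradient-boosted model on the full cohort feature table and
#' summarises feature importance as the mean absolute Shapley value per
#' feature (TreeSHAP, as implemented by xgboost's `predcontrib`), in
#' descending order.
#'
#' @inheritParams train_eval
#' @param features Output of [build_features()].
#' @param seed Integer seed for the refit.
#' @return A data.frame with columns `feature` and `mean_abs_shap`,
#'   descending.
#' @export
feature_attribution <- function(features, seed = 1) {
  x <- features$x; y <- features$y
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  fit <- .fit_gbt(x, y, seed)
  contrib <- stats::predict(fit, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
  contrib <- contrib[, !colnames(contrib) %in% c("BIAS", "(Intercept)"),
                     drop = FALSE]
  imp <- colMeans(abs(contrib))
  out <- data.frame(feature = names(imp), mean_abs_shap = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_shap), ]
  rownames(out) <- NULL
  out
}
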