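#' Pathology-specific logistic outcome model coefficients
#'
#' Returns the coefficients of the logistic outcome model used by the
#' synthetic cohort generator for one pathology. Each model is a linear
#' predictor on the logit scale, centred at pathology-specific reference
#' values:
#' \itemize{
#' \item AVM obliteration: `s (BED - BED50) - beta_v (V - v0) - beta_rt RT`
#'   with `s = 0.06`, `BED50 = 160` Gy_2.47, `beta_v = 0.05` per cc,
#'   `beta_rt = 0.5`; `v0` defaults to 5 cc.
#' \item VS control: `1.386 + 0.35 (BED - 58) - 0.10 (V - 4)` (Gy_3),
#'   i.e. 80% baseline control at BED 58 for a 4 cc tumour.
#' \item BM control: `1.5 + 0.07 (BED - 65) - 0.15 (V - 2)` (Gy_10).
#' \item MEN control: `-0.5 + 0.08 (BED - 70) - 0.04 (V - 5)` (Gy_3.5).
#' }
#'
#' @param pathology One of `"avm"`, `"vs"`, `"bm"`, `"men"`.
#' @return A named list of coefficients with the pathology tag.
#' @export
outcome_model_params <- function(pathology) {
  pathology <- tolower(as.character(pathology)[1L])
  switch(pathology,
    avm = list(pathology = "avm", s = 0.06, bed50 = 160,
               beta_v = 0.05, v0 = 5, beta_rt = 0.5),
    vs  = list(pathology = "vs", base_logit = 1.386, b_bed = 0.35,
               bed_ref = 58, b_vol = 0.10, vol_ref = 4),
    bm  = list(pathology = "bm", base_logit = 1.5, b_bed = 0.07,
               bed_ref = 65, b_vol = 0.15, vol_ref = 2),
    men = list(pathology = "men", base_logit = -0.5, b_bed = 0.08,
               bed_ref = 70, b_vol = 0.04, vol_ref = 5),
    stop("unknown pathology '", pathology, "'", call. = FALSE))
}

.outcome_logit <- function(params, bed, volume, prior_rt) {
  if (params$pathology == "avm") {
    params$s * (bed - params$bed50) - params$beta_v * (volume - params$v0) -
      params$beta_rt * prior_rt
  } else {
    params$base_logit + params$b_bed * (bed - params$bed_ref) -
      params$b_vol * (volume - params$vol_ref)
  }
}

#' Outcome probability under the pathology's logistic model
#'
#' Inverse-logit of the pathology-specific linear predictor; strictly
#' increasing in BED and strictly decreasing in volume. Prior radiotherapy
#' enters only the AVM model.
#'
#' @inheritParams outcome_model_params
#' @param bed Total course BED in the pathology's Gy_(alpha/beta) units (> 0).
#' @param volume Lesion volume in cc (> 0).
#' @param prior_rt Binary prior-radiotherapy indicator (AVM only; ignored
#'   elsewhere).
#' @param params Optional coefficient list overriding
#'   [outcome_model_params()] defaults.
#' @return Probability in (0, 1). Vectorised over `bed`, `volume`,
#'   `prior_rt`.
#' @examples
#' outcome_probability("vs", bed = 58, volume = 4)  # 0.8
#' @export
outcome_probability <- function(pathology, bed, volume, prior_rt = 0,
                                params = NULL) {
  if (any(bed <= 0)) stop("`bed` must be positive", call. = FALSE)
  if (any(volume <= 0)) stop("`volume` must be positive", call. = FALSE)
  if (is.null(params)) params <- outcome_model_params(pathology)
  stats::plogis(.outcome_logit(params, bed, volume, prior_rt))
}

#' Sample binary outcomes
#'
#' Independent Bernoulli draws from a vector of outcome probabilities,
#' reproducible given a seed.
#'
#' @param probs Probabilities in [0, 1].
#' @param seed Integer RNG seed.
#' @return Integer vector of 0/1 outcomes.
#' @export
sample_outcomes <- function(probs, seed) {
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("`probs` must lie in [0, 1]", call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  as.integer(stats::runif(length(probs)) < probs)
}
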