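#' Generator defaults for a synthetic cohort
#'
#' Returns the full set of constants behind [simulate_cohort()] for one
#' pathology: fractionation mix, per-scheme prescription dose ranges (total
#' dose for single-fraction schemes, per-fraction dose otherwise), volume
#' range, isocentre range and noise, beam-on and overhead time ranges, the
#' non-predictive covariate layout, and the outcome model coefficients.
#' All "range" quantities are sampled uniformly over the stated interval.
#' Any entry can be overridden through the `config` argument of
#' [simulate_cohort()].
#'
#' @inheritParams outcome_model_params
#' @return A named list of generator constants.
#' @export
cohort_defaults <- function(pathology) {
  pathology <- tolower(as.character(pathology)[1L])
  base <- switch(pathology,
    avm = list(
      fx_levels = c(1L, 3L, 5L), fx_probs = c(1, 1, 1) / 3,
      # dose_ranges[[as.character(F)]]: per-fraction dose range (Gy)
      dose_ranges = list(`1` = c(16, 24), `3` = c(7, 8), `5` = c(5, 6)),
      volume_range = c(1, 15),
      # 4-30 isocentres, scaled so the mean volume maps to the typical
      # AVM isocentre count (~12)
      iso_range = c(4, 30), iso_noise_sd = 2.6, iso_mean_at_mean_volume = 12,
      beam_on_range = c(2, 4), overhead_range = c(5, 10),
      locations = c("lobar", "deep", "cerebellar", "brainstem"),
      location_probs = c(0.25, 0.25, 0.25, 0.25),
      age_mean = 40, age_sd = 15, age_range = c(18, 80),
      p_prior_rt = 0.10, p_prior_surgery = 0.20,
      followup_range = c(2, 7)),
    vs = list(
      fx_levels = c(1L, 3L), fx_probs = c(0.7, 0.3),
      dose_ranges = list(`1` = c(11, 13), `3` = c(5.5, 7)),
      volume_range = c(0.5, 10),
      iso_range = c(3, 15), iso_noise_sd = 1.2,
      beam_on_range = c(1.5, 3), overhead_range = c(5, 8),
      locations = NULL),
    bm = list(
      fx_levels = c(1L, 3L, 5L), fx_probs = c(0.70, 0.25, 0.05),
      dose_ranges = list(`1` = c(18, 24), `3` = c(8, 10), `5` = c(5, 7)),
      volume_range = c(0.5, 8),
      iso_range = c(2, 12), iso_noise_sd = 1.0,
      beam_on_range = c(1.5, 3), overhead_range = c(4, 8),
      locations = c("supratentorial", "infratentorial"),
      location_probs = c(0.8, 0.2)),
    men = list(
      fx_levels = c(1L, 3L, 5L), fx_probs = c(0.50, 0.35, 0.15),
      dose_ranges = list(`1` = c(12, 16), `3` = c(7, 9), `5` = c(5, 6)),
      volume_range = c(1, 20),
      iso_range = c(4, 25), iso_noise_sd = 2.1,
      beam_on_range = c(2, 4), overhead_range = c(5, 12),
      locations = c("convexity", "skull_base", "parasagittal"),
      location_probs = c(1, 1, 1) / 3),
    stop("unknown pathology '", pathology, "'", call. = FALSE))
  base$pathology <- pathology
  base$outcome_params <- outcome_model_params(pathology)
  base
}

# isocentre count: linear in volume plus Gaussian noise, rounded and
# clipped to the stated range. By default the volume midpoint maps to the
# isocentre range midpoint; when a typical mean count is known
# (`iso_mean_at_mean_volume`) the line instead passes through
# (volume min, isocentre min) and (mean volume, typical mean count).
.draw_n_iso <- function(volume, cfg) {
  if (!is.null(cfg$iso_mean_at_mean_volume)) {
    v_mean <- mean(cfg$volume_range)
    b <- (cfg$iso_mean_at_mean_volume - cfg$iso_range[1L]) /
      (v_mean - cfg$volume_range[1L])
    a <- cfg$iso_range[1L] - b * cfg$volume_range[1L]
  } else {
    b <- diff(cfg$iso_range) / diff(cfg$volume_range)
    a <- cfg$iso_range[1L] - b * cfg$volume_range[1L]
  }
  n <- round(a + b * volume + stats::rnorm(1L, 0, cfg$iso_noise_sd))
  as.integer(min(cfg$iso_range[2L], max(cfg$iso_range[1L], n)))
}

#' Simulate a synthetic radiosurgery cohort
#'
#' Generates `n` synthetic patients for one pathology: covariates,
#' fractionation scheme, per-fraction prescription dose, isocentre count
#' (proportional to lesion volume with noise), beam-on and overhead times;
#' computes each patient's total course BED with the biexponential engine and
#' the pathology's kinetics; evaluates the pathology's logistic outcome model;
#' and samples the binary outcome. Each patient draws from an independent RNG
#' substream derived from `seed`, so records are reproducible bit-for-bit and
#' stable when `n` changes.
#'
#' @inheritParams outcome_model_params
#' @param n Number of patients (>= 1).
#' @param seed Integer root seed.
#' @param config Named list overriding any [cohort_defaults()] entry. The
#'   special entry `outcome = list(type = "bed_logit", beta0, beta1)` replaces
#'   the pathology outcome model with a plain logistic BED-response
#'   `logit p = beta0 + beta1 * BED` (used by the alpha/beta recovery
#'   experiment).
#' @param kinetics Optional [repair_kinetics()] override; defaults to
#'   [pathology_kinetics()] for the pathology.
#' @return A data.frame of class `bedfx_cohort`, one row per patient, with
#'   the fraction-level table in `attr(, "fractions")` and the kinetics,
#'   generator settings and seed attached as attributes.
#' @examples
#' coh <- simulate_cohort("vs", n = 20, seed = 1)
#' summary(coh$bed_total)
#' @export
simulate_cohort <- function(pathology, n, seed, config = list(),
                            kinetics = NULL) {
  cfg <- cohort_defaults(pathology)
  outcome_override <- config$outcome
  config$outcome <- NULL
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown generator setting(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(config)] <- config
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (is.null(kinetics)) kinetics <- pathology_kinetics(cfg$pathology)

  old <- .save_rng()
  on.exit(.restore_rng(old))

  is_avm <- cfg$pathology == "avm"
  rows <- vector("list", n)
  fx_rows <- vector("list", n)
  u_outcome <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(.mix_seed(seed, i))
    num_fx <- sample(cfg$fx_levels, 1L, prob = cfg$fx_probs)
    volume <- .runif1(cfg$volume_range[1L], cfg$volume_range[2L])
    location <- if (is.null(cfg$locations)) NA_character_ else
      sample(cfg$locations, 1L, prob = cfg$location_probs)
    if (is_avm) {
      age <- min(cfg$age_range[2L],
                 max(cfg$age_range[1L],
                     round(stats::rnorm(1L, cfg$age_mean, cfg$age_sd))))
      sex <- sample(c("f", "m"), 1L)
      prior_rt <- as.integer(stats::runif(1L) < cfg$p_prior_rt)
      prior_surgery <- as.integer(stats::runif(1L) < cfg$p_prior_surgery)
      followup <- .runif1(cfg$followup_range[1L], cfg$followup_range[2L])
    } else {
      age <- NA_integer_; sex <- NA_character_
      prior_rt <- 0L; prior_surgery <- 0L; followup <- NA_real_
    }
    dr <- cfg$dose_ranges[[as.character(num_fx)]]
    dose_fx <- .runif1(dr[1L], dr[2L])   # equal across fractions of a course
    n_iso <- beam_on <- overhead <- numeric(num_fx)
    for (j in seq_len(num_fx)) {
      n_iso[j] <- .draw_n_iso(volume, cfg)
      beam_on[j] <- .runif1(cfg$beam_on_range[1L], cfg$beam_on_range[2L])
      overhead[j] <- .runif1(cfg$overhead_range[1L], cfg$overhead_range[2L])
    }
    u_outcome[i] <- stats::runif(1L)
    pid <- sprintf("%s_%04d", cfg$pathology, i)
    fx_rows[[i]] <- data.frame(
      patient_id = pid, fraction_index = seq_len(num_fx),
      dose_gy = dose_fx, n_iso = n_iso,
      duration_min = n_iso * beam_on + overhead,
      beam_on_per_iso_min = beam_on, stringsAsFactors = FALSE)
    rows[[i]] <- data.frame(
      patient_id = pid, pathology = cfg$pathology, volume = volume,
      location = location, age = age, sex = sex, prior_rt = prior_rt,
      prior_surgery = prior_surgery, num_fractions = num_fx,
      dose_per_fraction = dose_fx, total_dose_gy = dose_fx * num_fx,
      n_iso_total = sum(n_iso),
      total_time_min = sum(n_iso * beam_on + overhead),
      followup_years = followup, stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, rows)
  fx <- do.call(rbind, fx_rows)

  bed <- bed_from_fractions(fx, kinetics)
  cohort$bed_total <- bed$bed_total[match(cohort$patient_id, bed$patient_id)]
  if (!is.null(outcome_override)) {
    if (!identical(outcome_override$type, "bed_logit"))
      stop("unsupported outcome override type", call. = FALSE)
    cohort$outcome_prob <- stats::plogis(
      outcome_override$beta0 + outcome_override$beta1 * cohort$bed_total)
  } else {
    cohort$outcome_prob <- outcome_probability(
      cfg$pathology, cohort$bed_total, cohort$volume, cohort$prior_rt,
      params = cfg$outcome_params)
  }
  cohort$outcome <- as.integer(u_outcome < cohort$outcome_prob)
  rownames(cohort) <- NULL
  structure(cohort,
            fractions = fx, pathology = cfg$pathology, kinetics = kinetics,
            seed = as.integer(seed), generator = cfg,
            class = c("bedfx_cohort", "data.frame"))
}

#' @export
print.bedfx_cohort <- function(x, ...) {
  cat(sprintf("Synthetic %s cohort: %d patients (seed %d)\n",
              toupper(attr(x, "pathology")), nrow(x), attr(x, "seed")))
  cat(sprintf("  BED total : median %.1f [%.1f-%.1f] Gy_%g\n",
              stats::median(x$bed_total), min(x$bed_total), max(x$bed_total),
              attr(x, "kinetics")$alpha_beta))
  cat(sprintf("  outcome   : %d/%d positive (%.1f%%)\n",
              sum(x$outcome), nrow(x), 100 * mean(x$outcome)))
  invisible(x)
}

#' Fraction table of a simulated cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @return The fraction-level data.frame attached to the cohort.
#' @export
cohort_fractions <- function(cohort) {
  fx <- attr(cohort, "fractions")
  if (is.null(fx)) stop("cohort carries no fraction table", call. = FALSE)
  fx
}

#' Write a cohort (and its fraction table) to CSV
#'
#' @param cohort A [simulate_cohort()] result.
#' @param path Output CSV path for the patient-level table.
#' @param fractions_path Optional output CSV path for the fraction table.
#' @export
write_cohort <- function(cohort, path, fractions_path = NULL) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  if (!is.null(fractions_path))
    write_fraction_table(cohort_fractions(cohort), fractions_path)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path Patient-level CSV path.
#' @param fractions_path Optional fraction-table CSV path; when given, the
#'   table is re-attached so BED-derived features can be rebuilt.
#' @param pathology Pathology tag to attach (recovered from the data when
#'   absent).
#' @return A `bedfx_cohort` data.frame.
#' @export
read_cohort <- function(path, fractions_path = NULL, pathology = NULL) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(pathology)) pathology <- cohort$pathology[1L]
  fx <- if (!is.null(fractions_path)) read_fraction_table(fractions_path)
  structure(cohort, fractions = fx, pathology = pathology,
            kinetics = pathology_kinetics(pathology), seed = NA_integer_,
            class = c("bedfx_cohort", "data.frame"))
}
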