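test_that("outcome models reproduce their reference points", {
  # AVM at the half-maximum point
  expect_equal(outcome_probability("avm", bed = 160, volume = 5), 0.5)
  # VS 80% baseline control at BED 58, 4 cc
  expect_equal(outcome_probability("vs", bed = 58, volume = 4), 0.8,
               tolerance = 2e-4)
  # MEN reference point, inverse-logit(-0.5)
  expect_equal(outcome_probability("men", bed = 70, volume = 5), 0.37754,
               tolerance = 1e-5)
  # BM baseline (the printed anchor 1.5 = logit(0.82) is slightly inexact;
  # the coefficient is used as printed)
  expect_equal(outcome_probability("bm", bed = 65, volume = 2),
               plogis(1.5))
  expect_error(outcome_probability("glioma", 60, 5), "unknown pathology")
  expect_error(outcome_probability("avm", -1, 5), "positive")
})

test_that("outcome probability is monotone and prior RT is AVM-specific", {
  beds <- seq(40, 90, by = 2)  # within range before the sigmoid saturates
  for (p in c("avm", "vs", "bm", "men")) {
    pr <- outcome_probability(p, beds, volume = 5)
    expect_true(all(diff(pr) > 0))
    expect_true(outcome_probability(p, 70, volume = 2) >
                  outcome_probability(p, 70, volume = 8))
  }
  expect_lt(outcome_probability("avm", 160, 5, prior_rt = 1), 0.5)
  expect_identical(outcome_probability("vs", 58, 4, prior_rt = 1),
                   outcome_probability("vs", 58, 4, prior_rt = 0))
})

test_that("outcome sampling is Bernoulli with the requested probabilities", {
  expect_identical(sample_outcomes(rep(0, 5), 1), rep(0L, 5))
  expect_identical(sample_outcomes(rep(1, 5), 1), rep(1L, 5))
  draws <- sample_outcomes(rep(0.5, 10000), seed = 11)
  expect_lt(abs(mean(draws) - 0.5), 0.015)  # 3 binomial SEs
  expect_identical(draws, sample_outcomes(rep(0.5, 10000), seed = 11))
  expect_error(sample_outcomes(c(0.5, 1.2), 1), "\\[0, 1\\]")
})

test_that("cohorts are reproducible and stable when n changes", {
  strip <- function(x) {
    x <- as.data.frame(x)
    data.frame(lapply(x, unname), stringsAsFactors = FALSE,
               row.names = NULL)
  }
  a <- simulate_cohort("avm", 40, seed = 123)
  b <- simulate_cohort("avm", 40, seed = 123)
  expect_identical(strip(a), strip(b))
  expect_identical(cohort_fractions(a), cohort_fractions(b))
  # per-patient substreams: the first 40 records of a larger cohort match
  big <- simulate_cohort("avm", 60, seed = 123)
  expect_identical(strip(a), strip(as.data.frame(big)[1:40, ]))
  expect_false(identical(strip(a),
                         strip(simulate_cohort("avm", 40, seed = 124))))
  expect_error(simulate_cohort("glioma", 10, 1), "unknown pathology")
})

test_that("generated plans respect the stated dose, geometry and time ranges", {
  specs <- list(
    avm = list(n = 300, fx = c(1, 3, 5), mix = c(1, 1, 1) / 3,
               dose = list(`1` = c(16, 24), `3` = c(7, 8), `5` = c(5, 6)),
               iso = c(4, 30), beam = c(2, 4), over = c(5, 10),
               vol = c(1, 15)),
    vs = list(n = 200, fx = c(1, 3), mix = c(0.7, 0.3),
              dose = list(`1` = c(11, 13), `3` = c(5.5, 7)),
              iso = c(3, 15), beam = c(1.5, 3), over = c(5, 8),
              vol = c(0.5, 10)),
    bm = list(n = 250, fx = c(1, 3, 5), mix = c(0.7, 0.25, 0.05),
              dose = list(`1` = c(18, 24), `3` = c(8, 10), `5` = c(5, 7)),
              iso = c(2, 12), beam = c(1.5, 3), over = c(4, 8),
              vol = c(0.5, 8)),
    men = list(n = 250, fx = c(1, 3, 5), mix = c(0.5, 0.35, 0.15),
               dose = list(`1` = c(12, 16), `3` = c(7, 9), `5` = c(5, 6)),
               iso = c(4, 25), beam = c(2, 4), over = c(5, 12),
               vol = c(1, 20)))
  for (p in names(specs)) {
    sp <- specs[[p]]
    coh <- simulate_cohort(p, sp$n, seed = 5)
    fx <- cohort_fractions(coh)
    expect_true(all(coh$num_fractions %in% sp$fx))
    expect_true(all(coh$volume >= sp$vol[1] & coh$volume <= sp$vol[2]))
    expect_true(all(fx$n_iso >= sp$iso[1] & fx$n_iso <= sp$iso[2]))
    expect_true(all(fx$beam_on_per_iso_min >= sp$beam[1] &
                      fx$beam_on_per_iso_min <= sp$beam[2]))
    overhead <- fx$duration_min - fx$n_iso * fx$beam_on_per_iso_min
    expect_true(all(overhead >= sp$over[1] - 1e-9 &
                      overhead <= sp$over[2] + 1e-9))
    for (f in sp$fx) {
      sel <- coh$num_fractions == f
      dr <- sp$dose[[as.character(f)]]
      expect_true(all(coh$dose_per_fraction[sel] >= dr[1] &
                        coh$dose_per_fraction[sel] <= dr[2]))
      # empirical mix within 3 binomial SEs of the stated probability
      pr <- sp$mix[match(f, sp$fx)]
      se <- sqrt(pr * (1 - pr) / sp$n)
      expect_lt(abs(mean(sel) - pr), 3 * se + 1e-9)
    }
    expect_true(all(coh$outcome %in% c(0L, 1L)))
    expect_true(all(coh$outcome_prob > 0 & coh$outcome_prob < 1))
    expect_true(all(coh$bed_total > 0))
  }
})

test_that("AVM covariates follow their stated construction", {
  coh <- simulate_cohort("avm", 300, seed = 2)
  expect_true(all(coh$followup_years >= 2 & coh$followup_years <= 7))
  expect_true(all(coh$location %in% c("lobar", "deep", "cerebellar",
                                      "brainstem")))
  expect_lt(abs(mean(coh$prior_rt) - 0.10), 3 * sqrt(0.1 * 0.9 / 300))
  expect_lt(abs(mean(coh$prior_surgery) - 0.20), 3 * sqrt(0.2 * 0.8 / 300))
  # BED recomputed from the fraction table matches the stored totals
  bed <- bed_from_fractions(cohort_fractions(coh), pathology_kinetics("avm"))
  expect_equal(coh$bed_total,
               bed$bed_total[match(coh$patient_id, bed$patient_id)])
})

test_that("dose-outcome coherence: responders carry higher BED", {
  gaps <- vapply(c("avm", "vs", "bm", "men"), function(p) {
    coh <- simulate_cohort(p, 250, seed = 3)
    mean(coh$bed_total[coh$outcome == 1]) -
      mean(coh$bed_total[coh$outcome == 0])
  }, numeric(1L))
  expect_true(all(gaps > 0))
  expect_gt(gaps[["avm"]], 40)  # tens of Gy for the steep AVM response
  expect_lt(gaps[["vs"]], 12)   # few Gy in the narrow VS band
})

test_that("VS BED values stay in the narrow clinical band", {
  coh <- simulate_cohort("vs", 200, seed = 4)
  expect_gt(min(coh$bed_total), 42)
  expect_lt(max(coh$bed_total), 73)
})

test_that("generator settings can be overridden and unknown keys rejected", {
  coh <- simulate_cohort("vs", 30, seed = 1,
                         config = list(volume_range = c(1, 2)))
  expect_true(all(coh$volume <= 2))
  expect_error(simulate_cohort("vs", 10, 1, config = list(alpha_betaa = 3)),
               "alpha_betaa")
})

test_that("cohorts round-trip through CSV", {
  coh <- simulate_cohort("bm", 25, seed = 9)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, p1, p2)
  back <- read_cohort(p1, p2)
  expect_equal(back$bed_total, coh$bed_total)
  expect_identical(attr(back, "pathology"), "bm")
  expect_equal(cohort_fractions(back)$dose_gy,
               cohort_fractions(coh)$dose_gy)
})
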