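test_that("repair rates derive from half-times", {
  expect_equal(repair_rate(1.0), log(2))
  expect_equal(repair_rate(0.19), 3.6481431, tolerance = 1e-7)
  expect_equal(repair_rate(2.16), 0.3209015, tolerance = 1e-6)
  expect_error(repair_rate(0), "positive")
  expect_error(repair_rate(-1), "positive")
  kin <- pathology_kinetics("avm")
  expect_identical(kin$mu_fast, log(2) / kin$halflife_fast)
  expect_identical(kin$mu_slow, log(2) / kin$halflife_slow)
})

test_that("incomplete-repair factor matches closed-form values and limits", {
  expect_identical(incomplete_repair_factor(1, 0), 1)
  expect_equal(incomplete_repair_factor(1, 1), 2 * exp(-1), tolerance = 1e-12)
  # value used by the 7-isocentre, 25.5-min reference session
  expect_equal(incomplete_repair_factor(repair_rate(0.19), 25.5 / 60),
               0.634471, tolerance = 1e-5)
  expect_error(incomplete_repair_factor(1, -0.1), "non-negative")
  expect_error(incomplete_repair_factor(0, 1), "positive")
})

test_that("incomplete-repair factor agrees with the double-integral oracle", {
  set.seed(7)
  for (i in 1:20) {
    mu <- runif(1, 0.05, 5)
    T_h <- runif(1, 0.01, 3)
    expect_equal(incomplete_repair_factor(mu, T_h), f_oracle(mu, T_h),
                 tolerance = 1e-6)
  }
})

test_that("incomplete-repair factor is decreasing with the 2/(muT) asymptote", {
  z <- 10^seq(-6, 3, length.out = 40)
  f <- incomplete_repair_factor(1, z)
  expect_true(all(f > 0 & f <= 1))
  expect_true(all(diff(f) < 0))
  # f * z / 2 -> 1 as z -> Inf
  expect_equal(f[length(f)] * z[length(z)] / 2, 1, tolerance = 2e-3)
  # series branch joins the closed form continuously around the threshold
  expect_lt(abs(incomplete_repair_factor(1, 0.99e-4) -
                  incomplete_repair_factor(1, 1.01e-4)), 1e-6)
})

test_that("session BED reproduces the hand-computed reference session", {
  s <- session_plan(8, 7, 25.5, 2.5)
  expect_equal(bed_session(s, avm_kin), 29.2283, tolerance = 1e-5)
  expect_equal(bed_session(s, avm_kin),
               bed_session_oracle(8, 7, 25.5, 2.5, avm_kin),
               tolerance = 1e-9)
})

test_that("session BED recovers the acute LQ limit as times vanish", {
  for (D in c(5, 12, 20, 24)) {
    for (n in c(1L, 7L, 20L)) {
      for (p in c("avm", "vs", "bm", "men")) {
        kin <- pathology_kinetics(p)
        acute <- bedfx:::.bed_session_vec(D, n, 1e-9, 1e-10, kin)
        expect_equal(acute, lq_bed(1, D, kin$alpha_beta),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("session BED is monotone in dose, duration and beam-on time", {
  kin <- avm_kin
  base <- bedfx:::.bed_session_vec(18, 10, 45, 3, kin)
  expect_true(bedfx:::.bed_session_vec(18.5, 10, 45, 3, kin) > base)
  expect_true(bedfx:::.bed_session_vec(18, 10, 50, 3, kin) < base)
  expect_true(bedfx:::.bed_session_vec(18, 10, 45, 3.5, kin) < base)
})

test_that("degenerate repair weights and equal rates collapse the mixture", {
  k1 <- repair_kinetics(2.47, 0.5, 0.5, 1)
  k0 <- repair_kinetics(2.47, 0.5, 0.5, 0)
  s <- session_plan(15, 8, 40, 3)
  expect_equal(bed_session(s, k1), bed_session(s, k0), tolerance = 1e-12)
  # equal rates make the result independent of the weight
  kx <- repair_kinetics(2.47, 0.5, 0.5, 0.3)
  expect_equal(bed_session(s, kx), bed_session(s, k1), tolerance = 1e-12)
})

test_that("course BED is additive over sessions in any order", {
  s1 <- session_plan(8, 7, 25.5, 2.5)
  s2 <- session_plan(10, 12, 50, 3.5)
  s3 <- session_plan(6, 5, 22, 2.2)
  total <- sum(vapply(list(s1, s2, s3), bed_session, numeric(1L),
                      kin = avm_kin))
  expect_equal(bed_course(course_plan(s1, s2, s3), avm_kin), total)
  expect_equal(bed_course(course_plan(s3, s1, s2), avm_kin), total)
  expect_equal(bed_course(course_plan(s1), avm_kin), bed_session(s1, avm_kin))
  expect_equal(bed_course(course_plan(s1, s1, s1), avm_kin),
               3 * bed_session(s1, avm_kin))
  expect_equal(bed_course(course_plan(s1, s1, s1), avm_kin), 87.69,
               tolerance = 1e-4)
})

test_that("classical LQ comparator matches its closed form", {
  expect_equal(lq_bed(1, 20, 2.47), 181.943, tolerance = 1e-5)
  expect_equal(lq_bed(3, 8, 2.47), 101.733, tolerance = 1e-5)
  # vanishing dose per fraction at fixed total dose: BED -> total dose
  expect_equal(lq_bed(1e6, 24 / 1e6, 2.47), 24, tolerance = 1e-4)
  expect_error(lq_bed(0, 8, 2.47), "positive")
})

test_that("carry-over adds a monotone inter-fraction interaction", {
  s <- session_plan(8, 7, 25.5, 2.5)
  course <- course_plan(s, s, s)
  base <- bed_course(course, avm_kin)
  expect_identical(bed_course_with_carryover(course, avm_kin, 0), base)
  v <- vapply(c(0, 0.05, 0.10, 0.20), bed_course_with_carryover,
              numeric(1L), course = course, kin = avm_kin)
  expect_true(all(diff(v) > 0))
  # a 5% carry-over adds an increment of order a few percent of the base
  rel <- (v[2L] - base) / base
  expect_gt(rel, 0.01)
  expect_lt(rel, 0.15)
  expect_error(bed_course_with_carryover(course, avm_kin, 1.2), "carry")
})

test_that("plan constructors enforce their invariants", {
  expect_error(session_plan(-1, 5, 30, 2), "positive")
  expect_error(session_plan(10, 0, 30, 2), "integer")
  expect_error(session_plan(10, 5, 8, 2), "overhead")
  expect_error(session_plan(10, 5, 30, 0), "positive")
  expect_error(course_plan(), "at least one")
})

test_that("fraction tables round-trip through CSV and match course BED", {
  fx <- make_fx_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_fraction_table(fx, path)
  fx2 <- read_fraction_table(path)
  expect_equal(fx2$dose_gy, fx$dose_gy)
  bed <- bed_from_fractions(fx2, avm_kin)
  courses <- courses_from_fraction_table(fx2)
  for (id in names(courses)) {
    expect_equal(bed$bed_total[bed$patient_id == id],
                 bed_course(courses[[id]], avm_kin))
  }
  # carry-over path agrees with the course-level function
  bed_c <- bed_from_fractions(fx2, avm_kin, carry = 0.1)
  expect_equal(bed_c$bed_total[bed_c$patient_id == "p2"],
               bed_course_with_carryover(courses[["p2"]], avm_kin, 0.1))
  bad <- fx; names(bad)[3] <- "dose"
  expect_error(bed_from_fractions(bad, avm_kin), "missing column")
})
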