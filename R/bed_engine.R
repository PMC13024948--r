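#' Incomplete-repair factor
#'
#' Dimensionless reduction of the quadratic (sublethal-damage interaction)
#' term when irradiation is protracted over a time `duration` with first-order
#' repair at rate `mu`:
#' \deqn{f(\mu T) = \frac{2}{\mu T}\left(1 - \frac{1 - e^{-\mu T}}{\mu T}\right)}
#' `f` equals 1 for instantaneous delivery and decays towards the asymptote
#' \eqn{2/(\mu T)} for long exposures. For very small arguments
#' (\eqn{\mu T < 10^{-4}}) the Taylor expansion
#' \eqn{1 - \mu T/3 + (\mu T)^2/12} is used to avoid catastrophic
#' cancellation.
#'
#' @param mu Repair rate in h^-1 (> 0).
#' @param duration Exposure time in hours (>= 0). Vectorised.
#' @return Values in (0, 1]; exactly 1 at `duration = 0`.
#' @examples
#' incomplete_repair_factor(1, 1)  # 2/e
#' @export
incomplete_repair_factor <- function(mu, duration) {
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("`mu` must be positive", call. = FALSE)
  if (any(!is.finite(duration)) || any(duration < 0))
    stop("`duration` must be non-negative", call. = FALSE)
  z <- mu * duration
  out <- numeric(length(z))
  small <- z < 1e-4
  zs <- z[small]
  out[small] <- 1 - zs / 3 + zs^2 / 12
  zl <- z[!small]
  out[!small] <- (2 / zl) * (1 - (1 - exp(-zl)) / zl)
  out
}

# vectorised engine core: dose/n_iso/T/t may be vectors (recycled),
# kinetics scalar. Times in minutes. Optionally overrides alpha/beta
# (used by the inference grid).
.bed_session_vec <- function(dose_total, n_iso, duration_min, beam_on_min,
                             kin, alpha_beta = kin$alpha_beta) {
  d <- dose_total / n_iso
  nd <- dose_total
  T_h <- duration_min / 60
  t_h <- beam_on_min / 60
  f1T <- incomplete_repair_factor(kin$mu_fast, T_h)
  f1t <- incomplete_repair_factor(kin$mu_fast, t_h)
  f2T <- incomplete_repair_factor(kin$mu_slow, T_h)
  f2t <- incomplete_repair_factor(kin$mu_slow, t_h)
  k <- alpha_beta
  fast <- 1 + ((nd - d) / k) * f1T + (d / k) * f1t
  slow <- 1 + ((nd - d) / k) * f2T + (d / k) * f2t
  kin$x_fast * nd * fast + (1 - kin$x_fast) * nd * slow
}

#' Session-level biologically effective dose
#'
#' Computes the BED of a single radiosurgical session under the biexponential
#' sublethal-damage repair model. With `n` isocentres each delivering
#' `d = D/n`, total session time `T` and mean beam-on time per isocentre `t`,
#' \deqn{BED = x\,nd\left[1 + \frac{nd-d}{k}f(\mu_1 T) + \frac{d}{k}f(\mu_1 t)\right]
#'  + (1-x)\,nd\left[1 + \frac{nd-d}{k}f(\mu_2 T) + \frac{d}{k}f(\mu_2 t)\right]}
#' where \eqn{k = \alpha/\beta}: interaction between isocentres is governed by
#' the session duration, interaction within an isocentre by its beam-on time.
#' In the acute limit (`T = t = 0`) this reduces to the classical LQ BED
#' `D (1 + D/k)`.
#'
#' @param plan A [session_plan()] object.
#' @param kin A [repair_kinetics()] object.
#' @return BED in Gy_(alpha/beta).
#' @examples
#' bed_session(session_plan(8, 7, 25.5, 2.5), pathology_kinetics("avm"))
#' @export
bed_session <- function(plan, kin) {
  if (!inherits(plan, "bedfx_session"))
    stop("`plan` must be a session_plan()", call. = FALSE)
  if (!inherits(kin, "bedfx_kinetics"))
    stop("`kin` must be a repair_kinetics()", call. = FALSE)
  .bed_session_vec(plan$dose_total, plan$n_iso, plan$duration_total,
                   plan$beam_on_per_iso, kin)
}

#' Course-level biologically effective dose
#'
#' Sums session BEDs over all fractions of a course, assuming complete
#' sublethal-damage repair between fractions (appropriate for ~24 h
#' inter-fraction intervals and the repair half-times modelled here).
#'
#' @param course A [course_plan()] object.
#' @inheritParams bed_session
#' @return Total course BED in Gy_(alpha/beta).
#' @seealso [bed_course_with_carryover()] for the sensitivity variant with
#'   partial inter-fraction repair.
#' @export
bed_course <- function(course, kin) {
  if (!inherits(course, "bedfx_course"))
    stop("`course` must be a course_plan()", call. = FALSE)
  if (length(course) < 1L) stop("empty course", call. = FALSE)
  sum(vapply(course, bed_session, numeric(1L), kin = kin))
}

#' Classical acute LQ biologically effective dose
#'
#' The standard linear-quadratic comparator `n d (1 + d / (alpha/beta))`,
#' which ignores intra-fraction protraction and repair.
#'
#' @param n_fractions Number of fractions (> 0).
#' @param dose_per_fraction Dose per fraction in Gy (> 0). Vectorised.
#' @param alpha_beta Alpha/beta ratio in Gy (> 0).
#' @return BED in Gy_(alpha/beta).
#' @examples
#' lq_bed(1, 20, 2.47)
#' @export
lq_bed <- function(n_fractions, dose_per_fraction, alpha_beta) {
  if (any(n_fractions <= 0) || any(dose_per_fraction <= 0) ||
      any(alpha_beta <= 0))
    stop("all arguments must be positive", call. = FALSE)
  n_fractions * dose_per_fraction * (1 + dose_per_fraction / alpha_beta)
}

#' Course BED with inter-fraction carry-over of sublethal damage
#'
#' Sensitivity variant relaxing the complete inter-fraction repair assumption.
#' A fraction `carry` of unrepaired sublethal damage persists to the next
#' fraction and interacts with its dose; the added term for a fraction pair
#' `(i, j)` with lag `l = j - i` is the Lea-Catcheside-style cross term
#' `carry^l * 2 D_i D_j / k`, split between the fast and slow damage
#' compartments with the same weights `x` and `1 - x` as the intra-fraction
#' terms (the compartment weights sum to one, so the split leaves the total
#' invariant but keeps the bookkeeping per compartment explicit). `carry = 0`
#' reproduces [bed_course()] exactly; the result is strictly increasing in
#' `carry`.
#'
#' @inheritParams bed_course
#' @param carry Carry-over fraction in [0, 1].
#' @return Total course BED in Gy_(alpha/beta).
#' @export
bed_course_with_carryover <- function(course, kin, carry = 0) {
  if (!is.numeric(carry) || length(carry) != 1L || !is.finite(carry) ||
      carry < 0 || carry > 1)
    stop("`carry` must be a single value in [0, 1]", call. = FALSE)
  base <- bed_course(course, kin)
  if (carry == 0 || length(course) == 1L) return(base)
  D <- vapply(course, `[[`, numeric(1L), "dose_total")
  k <- kin$alpha_beta
  extra <- 0
  FF <- length(D)
  for (i in seq_len(FF - 1L)) {
    for (j in seq.int(i + 1L, FF)) {
      cross <- carry^(j - i) * 2 * D[i] * D[j] / k
      extra <- extra + kin$x_fast * cross + (1 - kin$x_fast) * cross
    }
  }
  base + extra
}

#' Per-patient course BED from a fraction table
#'
#' Computes the total course BED for every patient in a fraction-level table
#' (see [read_fraction_table()]) under the given kinetics.
#'
#' @param fx Fraction table data.frame.
#' @inheritParams bed_session
#' @param carry Optional inter-fraction carry-over fraction, see
#'   [bed_course_with_carryover()].
#' @return A data.frame with columns `patient_id` and `bed_total`.
#' @export
bed_from_fractions <- function(fx, kin, carry = 0) {
  .validate_fraction_table(fx)
  session_bed <- .bed_session_vec(fx$dose_gy, fx$n_iso, fx$duration_min,
                                  fx$beam_on_per_iso_min, kin)
  totals <- tapply(session_bed, fx$patient_id, sum)
  out <- data.frame(patient_id = names(totals),
                    bed_total = as.numeric(totals),
                    stringsAsFactors = FALSE)
  if (carry > 0) {
    courses <- courses_from_fraction_table(fx)
    out$bed_total <- vapply(out$patient_id, function(id) {
      bed_course_with_carryover(courses[[id]], kin, carry)
    }, numeric(1L))
  }
  rownames(out) <- NULL
  out
}
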