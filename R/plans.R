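#' Single-session treatment plan
#'
#' Describes one radiosurgical session: the total physical dose, the number of
#' sequentially delivered isocentres (each contributing an equal dose
#' `dose_total / n_iso`), the total session duration and the mean beam-on time
#' per isocentre. Times are in minutes, matching treatment records; they are
#' converted to hours internally when repair rates are applied.
#'
#' @param dose_total Session physical dose in Gy (> 0).
#' @param n_iso Number of isocentres (>= 1).
#' @param duration_total Total session duration in minutes; must be at least
#'   `n_iso * beam_on_per_iso` (non-negative overhead).
#' @param beam_on_per_iso Mean beam-on time per isocentre in minutes (> 0).
#' @return An object of class `bedfx_session`.
#' @examples
#' session_plan(8, n_iso = 7, duration_total = 25.5, beam_on_per_iso = 2.5)
#' @export
session_plan <- function(dose_total, n_iso, duration_total, beam_on_per_iso) {
  v <- c(dose_total = dose_total, n_iso = n_iso,
         duration_total = duration_total, beam_on_per_iso = beam_on_per_iso)
  if (any(!is.finite(v))) stop("session plan fields must be finite", call. = FALSE)
  if (dose_total <= 0) stop("`dose_total` must be positive", call. = FALSE)
  if (n_iso < 1 || n_iso != round(n_iso))
    stop("`n_iso` must be a positive integer", call. = FALSE)
  if (beam_on_per_iso <= 0)
    stop("`beam_on_per_iso` must be positive", call. = FALSE)
  if (duration_total < n_iso * beam_on_per_iso)
    stop("`duration_total` must be >= n_iso * beam_on_per_iso ",
         "(overhead cannot be negative)", call. = FALSE)
  structure(list(dose_total = dose_total, n_iso = as.integer(n_iso),
                 duration_total = duration_total,
                 beam_on_per_iso = beam_on_per_iso),
            class = "bedfx_session")
}

#' Multi-session treatment course
#'
#' An ordered list of [session_plan()] objects, one per fraction.
#'
#' @param ... Session plans, or a single list of session plans.
#' @return An object of class `bedfx_course`.
#' @examples
#' s <- session_plan(8, 7, 25.5, 2.5)
#' course_plan(s, s, s)
#' @export
course_plan <- function(...) {
  sessions <- list(...)
  if (length(sessions) == 1L && !inherits(sessions[[1L]], "bedfx_session"))
    sessions <- sessions[[1L]]
  if (length(sessions) < 1L) stop("a course needs at least one session", call. = FALSE)
  ok <- vapply(sessions, inherits, logical(1L), what = "bedfx_session")
  if (!all(ok)) stop("all elements must be `session_plan()` objects", call. = FALSE)
  structure(sessions, class = "bedfx_course")
}

#' @export
print.bedfx_session <- function(x, ...) {
  cat(sprintf("Session: %.3g Gy over %d isocentres, %.3g min total (%.3g min beam-on/iso)\n",
              x$dose_total, x$n_iso, x$duration_total, x$beam_on_per_iso))
  invisible(x)
}

#' @export
print.bedfx_course <- function(x, ...) {
  cat(sprintf("Course with %d fraction(s), total %.3g Gy\n", length(x),
              sum(vapply(x, `[[`, numeric(1L), "dose_total"))))
  for (s in x) print(s)
  invisible(x)
}

.fraction_cols <- c("patient_id", "fraction_index", "dose_gy", "n_iso",
                    "duration_min", "beam_on_per_iso_min")

.validate_fraction_table <- function(fx) {
  missing <- setdiff(.fraction_cols, names(fx))
  if (length(missing))
    stop("fraction table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(fx$dose_gy <= 0)) stop("fraction doses must be positive", call. = FALSE)
  if (any(fx$n_iso < 1)) stop("isocentre counts must be >= 1", call. = FALSE)
  if (any(fx$beam_on_per_iso_min <= 0))
    stop("beam-on times must be positive", call. = FALSE)
  if (any(fx$duration_min < fx$n_iso * fx$beam_on_per_iso_min - 1e-9))
    stop("session duration must cover n_iso * beam-on time", call. = FALSE)
  invisible(fx)
}

#' Read or write a fraction-level treatment table
#'
#' The fraction table is the on-disk exchange format for treatment courses:
#' one row per delivered fraction with columns `patient_id, fraction_index,
#' dose_gy, n_iso, duration_min, beam_on_per_iso_min` (UTF-8 CSV, header
#' required, '.' decimal).
#'
#' @param path File path.
#' @return `read_fraction_table()` returns a validated data.frame.
#' @export
read_fraction_table <- function(path) {
  fx <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_fraction_table(fx)
  fx[order(fx$patient_id, fx$fraction_index), , drop = FALSE]
}

#' @rdname read_fraction_table
#' @param fx A fraction table data.frame.
#' @export
write_fraction_table <- function(fx, path) {
  .validate_fraction_table(fx)
  utils::write.csv(fx[, .fraction_cols], path, row.names = FALSE)
  invisible(path)
}

#' Convert fraction-table rows into course plans
#'
#' @param fx A fraction table (see [read_fraction_table()]).
#' @return A named list of [course_plan()] objects, one per patient.
#' @export
courses_from_fraction_table <- function(fx) {
  .validate_fraction_table(fx)
  split_fx <- split(fx, fx$patient_id)
  lapply(split_fx, function(d) {
    d <- d[order(d$fraction_index), ]
    course_plan(lapply(seq_len(nrow(d)), function(i) {
      session_plan(d$dose_gy[i], d$n_iso[i], d$duration_min[i],
                   d$beam_on_per_iso_min[i])
    }))
  })
}
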