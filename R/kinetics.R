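#' Repair rate from a half-time
#'
#' Converts a sublethal-damage repair half-time into a first-order repair
#' rate, \eqn{\mu = \ln 2 / T_{1/2}}.
#'
#' @param halflife_h Repair half-time in hours. Must be positive.
#' @return Repair rate in h^-1.
#' @examples
#' repair_rate(0.19)  # fast CNS-like component, ~3.648 h^-1
#' @export
repair_rate <- function(halflife_h) {
  if (!is.numeric(halflife_h) || any(!is.finite(halflife_h)) ||
      any(halflife_h <= 0)) {
    stop("`halflife_h` must be a positive finite number", call. = FALSE)
  }
  log(2) / halflife_h
}

#' Radiobiological parameter set
#'
#' Bundles the parameters of the biexponential-repair linear-quadratic model:
#' the alpha/beta ratio, fast and slow repair half-times, and the weight of
#' the fast repair component. Repair rates `mu_fast` and `mu_slow` are derived
#' as ln(2)/half-time.
#'
#' @param alpha_beta Alpha/beta ratio in Gy (> 0).
#' @param halflife_fast Fast repair half-time in hours (> 0).
#' @param halflife_slow Slow repair half-time in hours (>= `halflife_fast`).
#' @param x_fast Fraction of sublethal damage assigned to the fast component,
#'   in [0, 1].
#' @param pathology Optional pathology label carried along for display.
#' @return An object of class `bedfx_kinetics`.
#' @seealso [pathology_kinetics()] for the built-in pathology sets.
#' @examples
#' repair_kinetics(2.47, 0.19, 2.16, 1 / 1.98)
#' @export
repair_kinetics <- function(alpha_beta, halflife_fast, halflife_slow, x_fast,
                            pathology = NA_character_) {
  stopifnot(is.numeric(alpha_beta), length(alpha_beta) == 1L,
            is.numeric(halflife_fast), length(halflife_fast) == 1L,
            is.numeric(halflife_slow), length(halflife_slow) == 1L,
            is.numeric(x_fast), length(x_fast) == 1L)
  if (!is.finite(alpha_beta) || alpha_beta <= 0)
    stop("`alpha_beta` must be positive", call. = FALSE)
  if (!is.finite(halflife_fast) || halflife_fast <= 0)
    stop("`halflife_fast` must be positive", call. = FALSE)
  if (!is.finite(halflife_slow) || halflife_slow < halflife_fast)
    stop("`halflife_slow` must be >= `halflife_fast`", call. = FALSE)
  if (!is.finite(x_fast) || x_fast < 0 || x_fast > 1)
    stop("`x_fast` must lie in [0, 1]", call. = FALSE)
  structure(
    list(alpha_beta = alpha_beta,
         halflife_fast = halflife_fast,
         halflife_slow = halflife_slow,
         x_fast = x_fast,
         mu_fast = repair_rate(halflife_fast),
         mu_slow = repair_rate(halflife_slow),
         pathology = pathology),
    class = "bedfx_kinetics")
}

# registry cache for the shipped parameter sets
.bedfx_registry <- new.env(parent = emptyenv())

.load_pathology_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.bedfx_registry$builtin)) return(.bedfx_registry$builtin)
    path <- system.file("extdata", "pathologies.yaml", package = "bedfx")
    reg <- yaml::read_yaml(path)
    .bedfx_registry$builtin <- reg
    return(reg)
  }
  yaml::read_yaml(path)
}

#' Built-in pathology radiobiological parameter sets
#'
#' Returns the shipped parameter set for one of the four modelled pathologies:
#' arteriovenous malformation (`"avm"`), vestibular schwannoma (`"vs"`),
#' brain metastasis (`"bm"`) or meningioma (`"men"`). Sets are stored in
#' `inst/extdata/pathologies.yaml`; an alternative registry file with the
#' same keys (`alpha_beta_gy`, `t_half_fast_h`, `t_half_slow_h`, `x_fast`)
#' can be supplied.
#'
#' @param pathology One of `"avm"`, `"vs"`, `"bm"`, `"men"` (or a key of the
#'   supplied registry file).
#' @param registry Optional path to a YAML registry overriding the built-in
#'   sets.
#' @return A [repair_kinetics()] object.
#' @examples
#' pathology_kinetics("avm")
#' @export
pathology_kinetics <- function(pathology, registry = NULL) {
  reg <- .load_pathology_registry(registry)
  pathology <- tolower(as.character(pathology)[1L])
  if (!pathology %in% names(reg)) {
    stop("unknown pathology '", pathology, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  p <- reg[[pathology]]
  repair_kinetics(p$alpha_beta_gy, p$t_half_fast_h, p$t_half_slow_h,
                  p$x_fast, pathology = pathology)
}

#' @export
print.bedfx_kinetics <- function(x, ...) {
  cat("Radiobiological parameters",
      if (!is.na(x$pathology)) paste0("(", x$pathology, ")"), "\n")
  cat(sprintf("  alpha/beta      : %.3g Gy\n", x$alpha_beta))
  cat(sprintf("  fast repair     : T1/2 = %.3g h (mu = %.4g 1/h), weight %.3g\n",
              x$halflife_fast, x$mu_fast, x$x_fast))
  cat(sprintf("  slow repair     : T1/2 = %.3g h (mu = %.4g 1/h), weight %.3g\n",
              x$halflife_slow, x$mu_slow, 1 - x$x_fast))
  invisible(x)
}
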