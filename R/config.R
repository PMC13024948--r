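#' Default pipeline configuration
#'
#' The full configuration consumed by [run_all()]: which stages run, cohort
#' sizes, seeds and output directory, plus per-stage settings. Every
#' stochastic step has an explicit seed derived from `seed` unless
#' overridden.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 42L,
    out_dir = "bedfx_output",
    pathologies = c("avm", "vs", "bm", "men"),
    cohort = list(n_avm = 300L, n_vs = 200L, n_bm = 250L, n_men = 250L),
    ml = list(models = c("gbt"), families = c("A", "B", "C"),
              bootstrap = 200L, cv_folds = 5L),
    bayes = list(enabled = TRUE, n_patients = 1000L, grid_size = 60L,
                 chains = 4L, warmup = 1500L, draws = 1500L,
                 beta0 = -5, beta1 = 0.05),
    surrogate = list(enabled = TRUE, n_courses = 5000L, epochs = 500L),
    planning = list(enabled = TRUE, n_points = 30L),
    stages = list(simulate = TRUE, ml = TRUE, univariate = TRUE,
                  bayes = TRUE, surrogate = TRUE, planning = TRUE))
}

.merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop("unknown configuration key: '", full, "'", call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key '", full, "' must be a mapping",
             call. = FALSE)
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                       c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration file
#'
#' Reads a YAML or JSON configuration, rejects unknown keys (naming the
#' offending key), and fills every unspecified entry from
#' [default_config()]. An empty file yields all defaults.
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`). `NULL`
#'   returns the defaults.
#' @return A validated configuration list.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config must be a mapping", call. = FALSE)
  .merge_config(defaults, user)
}
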