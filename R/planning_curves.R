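#' Monotone standardized logistic planning surrogate
#'
#' Fits a 3-feature logistic regression (total BED, lesion volume, prior
#' radiotherapy; each z-scored with training statistics) to the synthetic
#' AVM cohort. Logistic regression is used deliberately instead of a tree
#' ensemble: its predictions are strictly monotone in each standardized
#' feature, so planning curves swept over continuous dose grids cannot
#' oscillate. Held-out discrimination/calibration are estimated on a
#' stratified 75/25 split; the coefficients used for curve generation are
#' then refit on the full cohort (set `refit_full = FALSE` to keep the
#' split fit).
#'
#' @param cohort An AVM [simulate_cohort()] result with both outcomes
#'   present.
#' @param seed Integer seed for the evaluation split.
#' @param refit_full Refit on the full cohort after held-out evaluation
#'   (default TRUE).
#' @return An object of class `bedfx_logit_surrogate`: coefficients,
#'   standardization constants, and held-out `auc` / `brier`.
#' @export
fit_logistic_surrogate <- function(cohort, seed = 1, refit_full = TRUE) {
  if (!identical(attr(cohort, "pathology"), "avm"))
    stop("the planning surrogate is fit on the AVM cohort", call. = FALSE)
  y <- as.integer(cohort$outcome)
  if (length(unique(y)) < 2L)
    stop("cohort must contain both outcomes", call. = FALSE)
  X <- cbind(bed = cohort$bed_total, volume = cohort$volume,
             prior_rt = cohort$prior_rt)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  train <- .stratified_split(y, 0.75)

  fit_on <- function(idx) {
    mu <- colMeans(X[idx, , drop = FALSE])
    sdv <- apply(X[idx, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1
    Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
    df <- data.frame(y = y, Z)
    fit <- suppressWarnings(stats::glm(y ~ bed + volume + prior_rt,
                                       data = df[idx, ],
                                       family = stats::binomial()))
    cf <- stats::coef(fit)
    # ridge fallback on detected separation (diverging coefficients)
    if (anyNA(cf) || any(abs(cf) > 20) || !fit$converged) {
      cf <- .ridge_logit(cbind(1, Z[idx, , drop = FALSE]), y[idx])
      names(cf) <- c("(Intercept)", colnames(Z))
    }
    list(coef = cf, mu = mu, sd = sdv, Z = Z)
  }

  f_train <- fit_on(which(train))
  preds_test <- stats::plogis(
    cbind(1, f_train$Z[!train, , drop = FALSE]) %*% f_train$coef)
  auc <- auc_score(as.numeric(preds_test), y[!train])
  brier <- brier_score(as.numeric(preds_test), y[!train])

  f_final <- if (refit_full) fit_on(seq_along(y)) else f_train
  if (f_final$coef[["bed"]] <= 0)
    warning("fitted BED coefficient is not positive; predictions are not ",
            "increasing in BED", call. = FALSE)
  structure(
    list(coef = f_final$coef, mu = f_final$mu, sd = f_final$sd,
         auc = auc, brier = brier, n_test = sum(!train),
         refit_full = refit_full, seed = seed),
    class = "bedfx_logit_surrogate")
}

# ridge-penalised logistic IRLS; keeps coefficients finite under complete
# separation (penalty small enough to be negligible otherwise)
.ridge_logit <- function(x, y, lambda = 1e-2) {
  p <- ncol(x)
  beta <- rep(0, p)
  for (i in seq_len(200L)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(crossprod(x, w * x) + diag(lambda, p),
                           crossprod(x, w * z)))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta
}

#' @export
predict.bedfx_logit_surrogate <- function(object, newdata, ...) {
  X <- cbind(bed = newdata$bed, volume = newdata$volume,
             prior_rt = newdata$prior_rt)
  Z <- sweep(sweep(X, 2L, object$mu), 2L, object$sd, "/")
  as.numeric(stats::plogis(cbind(1, Z) %*% object$coef))
}

#' @export
coef.bedfx_logit_surrogate <- function(object, ...) object$coef

#' @export
print.bedfx_logit_surrogate <- function(x, ...) {
  cat("Standardized logistic planning surrogate (BED, volume, prior RT)\n")
  cat(sprintf("  held-out AUC %.3f, Brier %.3f (n_test = %d)\n",
              x$auc, x$brier, x$n_test))
  cat("  coefficients (standardized scale):\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' Virtual fractionation plan grid
#'
#' Builds the 90 virtual prescriptions swept by the planning module: three
#' canonical schemes (1 fraction 18-24 Gy, 3 fractions 27-33 Gy total,
#' 5 fractions 30-40 Gy total), 30 uniformly spaced total doses each, with
#' standardized geometry (7 isocentres per fraction, 2.5 min per isocentre,
#' 8 min overhead) and equal per-fraction doses.
#'
#' @param n_points Doses per scheme (default 30).
#' @return A data.frame with one row per virtual plan: scheme, fraction
#'   count, total and per-fraction dose, and the fixed time structure.
#' @export
virtual_plan_grid <- function(n_points = 30) {
  schemes <- list(list(num_fx = 1L, range = c(18, 24)),
                  list(num_fx = 3L, range = c(27, 33)),
                  list(num_fx = 5L, range = c(30, 40)))
  do.call(rbind, lapply(schemes, function(s) {
    total <- seq(s$range[1L], s$range[2L], length.out = n_points)
    data.frame(scheme = paste0(s$num_fx, "fx"), num_fx = s$num_fx,
               total_dose_gy = total, dose_per_fx = total / s$num_fx,
               n_iso = 7L, beam_on_per_iso_min = 2.5, overhead_min = 8,
               stringsAsFactors = FALSE)
  }))
}

#' Sweep planning curves over virtual prescriptions
#'
#' For each virtual plan the full fraction-resolved engine computes the
#' course BED under AVM kinetics, and the logistic surrogate predicts the
#' control probability for a virtual patient (default: 5 cc lesion, no
#' prior radiotherapy). Plotted against total dose the three schemes
#' separate (1 fx > 3 fx > 5 fx at matched dose); plotted against BED they
#' collapse onto a single curve, because the surrogate depends on dose only
#' through BED.
#'
#' @param model A [fit_logistic_surrogate()] result.
#' @param grid A [virtual_plan_grid()] data.frame.
#' @param volume Virtual patient lesion volume in cc (default 5).
#' @param prior_rt Virtual patient prior-radiotherapy flag (default 0).
#' @param kin Kinetics for the BED computation (default AVM).
#' @return A data.frame of class `bedfx_planning_curves` with columns
#'   `scheme, num_fx, total_dose_gy, bed_gy, prob`.
#' @export
sweep_planning_curves <- function(model, grid = virtual_plan_grid(),
                                  volume = 5, prior_rt = 0,
                                  kin = pathology_kinetics("avm")) {
  if (!inherits(model, "bedfx_logit_surrogate"))
    stop("`model` must be a fit_logistic_surrogate() result", call. = FALSE)
  duration <- grid$n_iso * grid$beam_on_per_iso_min + grid$overhead_min
  bed_fx <- .bed_session_vec(grid$dose_per_fx, grid$n_iso, duration,
                             grid$beam_on_per_iso_min, kin)
  bed <- bed_fx * grid$num_fx    # identical fractions, complete repair
  prob <- predict(model, data.frame(bed = bed, volume = volume,
                                    prior_rt = prior_rt))
  out <- data.frame(scheme = grid$scheme, num_fx = grid$num_fx,
                    total_dose_gy = grid$total_dose_gy, bed_gy = bed,
                    prob = prob, stringsAsFactors = FALSE)
  class(out) <- c("bedfx_planning_curves", "data.frame")
  attr(out, "virtual_patient") <- list(volume = volume, prior_rt = prior_rt)
  out
}

#' @export
plot.bedfx_planning_curves <- function(x, axis = c("dose", "bed"), ...) {
  axis <- match.arg(axis)
  xs <- if (axis == "dose") x$total_dose_gy else x$bed_gy
  xlab <- if (axis == "dose") "Total physical dose (Gy)" else
    expression(BED[2.47] * " (Gy)")
  schemes <- unique(x$scheme)
  graphics::plot(range(xs), c(0, 1), type = "n", xlab = xlab,
                 ylab = "Predicted control probability", ...)
  for (i in seq_along(schemes)) {
    sel <- x$scheme == schemes[i]
    graphics::lines(xs[sel], x$prob[sel], col = i, lwd = 2)
  }
  graphics::legend("bottomright", legend = schemes, col = seq_along(schemes),
                   lwd = 2, bty = "n")
  invisible(x)
}
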