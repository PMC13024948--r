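#' Synthetic treatment courses for surrogate training
#'
#' Samples Gamma Knife treatment courses with randomised fractionation (1, 3
#' or 5 fractions), total doses of 16-24 Gy (1 fx), 21-24 Gy (3 fx) or
#' 25-30 Gy (5 fx), 4-30 isocentres per fraction, 2-4 min mean beam-on time
#' per isocentre and 5-15 min per-fraction overhead; computes the
#' ground-truth course BED with the biexponential engine under AVM kinetics;
#' and assembles the 7-element course feature vector
#' (`num_fx`, `d_per_fx`, `total_d`, `n_iso_mean`, `n_iso_total`,
#' `t_min_mean`, `t_min_total`).
#'
#' @param n Number of courses (default 5000).
#' @param seed Integer seed.
#' @return A list of class `bedfx_surrogate_data` with the feature matrix
#'   `x`, target vector `bed` (Gy_2.47) and the raw fraction table.
#' @export
generate_surrogate_dataset <- function(n = 5000, seed = 1) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  kin <- pathology_kinetics("avm")
  num_fx <- sample(c(1L, 3L, 5L), n, replace = TRUE)
  total_rng <- list(`1` = c(16, 24), `3` = c(21, 24), `5` = c(25, 30))
  total_d <- vapply(num_fx, function(f) {
    r <- total_rng[[as.character(f)]]
    stats::runif(1L, r[1L], r[2L])
  }, numeric(1L))
  d_per_fx <- total_d / num_fx
  # per-fraction geometry/time draws
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- num_fx[i]
    n_iso <- pmin(pmax(stats::rpois(f, 12), 4L), 30L)  # 4-30, mean ~12
    beam_on <- stats::runif(f, 2, 4)
    overhead <- stats::runif(f, 5, 15)
    rows[[i]] <- data.frame(
      patient_id = sprintf("c%05d", i), fraction_index = seq_len(f),
      dose_gy = d_per_fx[i], n_iso = n_iso,
      duration_min = n_iso * beam_on + overhead,
      beam_on_per_iso_min = beam_on, stringsAsFactors = FALSE)
  }
  fx <- do.call(rbind, rows)
  bed <- bed_from_fractions(fx, kin)
  ids <- sprintf("c%05d", seq_len(n))
  bed_total <- bed$bed_total[match(ids, bed$patient_id)]
  n_iso_mean <- as.numeric(tapply(fx$n_iso, fx$patient_id, mean)[ids])
  n_iso_total <- as.numeric(tapply(fx$n_iso, fx$patient_id, sum)[ids])
  t_mean <- as.numeric(tapply(fx$duration_min, fx$patient_id, mean)[ids])
  t_total <- as.numeric(tapply(fx$duration_min, fx$patient_id, sum)[ids])
  x <- cbind(num_fx = as.numeric(num_fx), d_per_fx = d_per_fx,
             total_d = total_d, n_iso_mean = n_iso_mean,
             n_iso_total = n_iso_total, t_min_mean = t_mean,
             t_min_total = t_total)
  structure(list(x = x, bed = bed_total, fractions = fx, kinetics = kin,
                 seed = as.integer(seed)),
            class = "bedfx_surrogate_data")
}

# ---- minimal multilayer perceptron with Adam ------------------------------
# Two hidden ReLU layers; mean-squared-error loss; mini-batch Adam with the
# scikit-learn-style defaults (batch 200, lr 1e-3). Inputs and targets are
# z-scored with training statistics; predictions are mapped back to Gy.

.mlp_init <- function(sizes, seed) {
  set.seed(as.integer(seed))
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    # Glorot uniform
    r <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -r, r),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

.mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% par$W[[l]] + rep(par$b[[l]], each = nrow(A[[l]]))
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  A
}

.mlp_train <- function(X, y, hidden = c(64, 64), epochs = 500,
                       batch_size = 200, lr = 1e-3, seed = 1) {
  sizes <- c(ncol(X), hidden, 1L)
  par <- .mlp_init(sizes, seed)
  L <- length(par$W)
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(X); t_step <- 0L
  set.seed(.mix_seed(seed, 1L, stream = 5L))
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq.int(1L, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      A <- .mlp_forward(par, Xb)
      m <- length(idx)
      delta <- 2 * (A[[L + 1L]] - yb) / m      # dLoss/dZ_out, MSE
      t_step <- t_step + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(par$W[[l]])) * (A[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^t_step)
        vhW <- vW[[l]] / (1 - beta2^t_step)
        mhb <- mb[[l]] / (1 - beta1^t_step)
        vhb <- vb[[l]] / (1 - beta2^t_step)
        par$W[[l]] <- par$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
  }
  par
}

#' Train the neural BED surrogate
#'
#' Fits a feed-forward regressor (two hidden layers of 64 ReLU units, Adam
#' optimiser, mean-squared-error loss, 500 training epochs with mini-batches
#' of 200) that maps the 7 course-level features to the engine-computed BED,
#' on an 80/20 train/test split. Features and targets are standardized with
#' training statistics; reported metrics are on the held-out 20% in Gy.
#'
#' @param dataset A [generate_surrogate_dataset()] result (>= 100 rows).
#' @param seed Integer seed for the split, initialisation and batching.
#' @param epochs Training epochs (default 500).
#' @return An object of class `bedfx_mlp` with the fitted weights, scaling
#'   constants, and held-out `r2` and `mae`.
#' @export
train_surrogate <- function(dataset, seed = 1, epochs = 500) {
  x <- dataset$x; y <- dataset$bed
  if (nrow(x) < 100) stop("dataset must have >= 100 rows", call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- nrow(x)
  test <- sample.int(n, round(0.2 * n))
  train <- setdiff(seq_len(n), test)
  mu_x <- colMeans(x[train, , drop = FALSE])
  sd_x <- apply(x[train, , drop = FALSE], 2L, stats::sd)
  sd_x[sd_x == 0] <- 1
  mu_y <- mean(y[train]); sd_y <- stats::sd(y[train])
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  Xz <- sweep(sweep(x, 2L, mu_x), 2L, sd_x, "/")
  yz <- (y - mu_y) / sd_y
  par <- .mlp_train(Xz[train, , drop = FALSE], yz[train], seed = seed,
                    epochs = epochs)
  model <- structure(
    list(par = par, mu_x = mu_x, sd_x = sd_x, mu_y = mu_y, sd_y = sd_y,
         feature_names = colnames(x), seed = seed, epochs = epochs,
         n_train = length(train), n_test = length(test)),
    class = "bedfx_mlp")
  preds <- predict(model, x[test, , drop = FALSE])
  resid <- y[test] - preds
  ss_res <- sum(resid^2)
  ss_tot <- sum((y[test] - mean(y[test]))^2)
  model$r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  model$mae <- mean(abs(resid))
  model$test_index <- test
  model
}

#' @export
predict.bedfx_mlp <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$feature_names %in% colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  Xz <- sweep(sweep(newdata, 2L, object$mu_x), 2L, object$sd_x, "/")
  A <- .mlp_forward(object$par, Xz)
  as.numeric(A[[length(A)]]) * object$sd_y + object$mu_y
}

#' @export
print.bedfx_mlp <- function(x, ...) {
  cat("Neural BED surrogate (2 x 64 ReLU, Adam)\n")
  cat(sprintf("  trained on %d courses, evaluated on %d held out\n",
              x$n_train, x$n_test))
  if (!is.null(x$r2))
    cat(sprintf("  held-out R^2 = %.4f, MAE = %.3f Gy\n", x$r2, x$mae))
  invisible(x)
}
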