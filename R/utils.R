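# shared internal helpers

# Save/restore the global RNG state so exported functions that seed
# internally do not disturb the caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Deterministic substream seed for unit i under root `seed`; kept inside
# 32-bit integer range. Distinct streams per (seed, stream, i).
.mix_seed <- function(seed, i, stream = 0L) {
  m <- 2147483629
  s <- (as.double(seed) %% m) * 48271 %% m
  s <- (s + as.double(i) * 9973 + as.double(stream) * 7919001) %% m
  as.integer(s)
}

.runif1 <- function(lo, hi) stats::runif(1L, lo, hi)

# stratified split indices: returns logical vector TRUE = train
.stratified_split <- function(labels, train_frac = 0.75) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_train <- round(length(idx) * train_frac)
    n_train <- max(1L, min(length(idx) - 1L, n_train))
    train[sample(idx, n_train)] <- TRUE
  }
  train
}

# stratified k-fold assignment
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# tiny FNV-1a hash of a serialised R object (hex string); used to stamp
# outputs with their configuration
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
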