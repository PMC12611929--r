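# Shared helpers: independent brute-force oracles and small fixture builders.

# Exhaustive Otsu oracle: try all 256 candidate thresholds, compute the
# between-class variance from first principles, return the smallest maximizer.
otsu_brute_force <- function(image) {
  v <- pmin(pmax(round(as.numeric(image)), 0), 255)
  best_t <- NA_integer_
  best_var <- -Inf
  for (t in 0:255) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    w1 <- 1 - w0
    bc <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bc > best_var + 1e-12) {
      best_var <- bc
      best_t <- t
    }
  }
  best_t
}

# Mann-Whitney AUC by exhaustive pair comparison (half credit for ties).
auc_pairwise <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Random probability matrix with rows summing to 1.
random_probs <- function(n, k) {
  p <- matrix(rexp(n * k), n, k)
  p / rowSums(p)
}

# Minimal slice tibble with random pixels (for split/augment/train tests that
# do not need phantom structure).
random_slices <- function(n, grades = 0:4, size = 224, set = "train",
                          prefix = "P") {
  tibble::tibble(
    patient_id = sprintf("%s%03d", prefix, seq_len(n)),
    side = rep_len(c("left", "right"), n),
    grade = sample(grades, n, replace = TRUE),
    pain = FALSE,
    pixels = lapply(seq_len(n), function(i) matrix(runif(size * size), size)),
    augmented = FALSE,
    set = set
  )
}

# Scale a phantom truth box's columns into standardized-image coordinates.
scale_truth_cols <- function(truth_box, native_width, size = 224) {
  sc <- size / native_width
  c(start = truth_box[["col_start"]] * sc, end = truth_box[["col_end"]] * sc)
}
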