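# Shared low-level helpers: seed derivation, image resizing/blurring, checks.

#' Derive a per-stage seed from a global seed
#'
#' Fans one global seed out to independent per-stage seeds so that pipeline
#' stages can be re-run in isolation. Uses a multiplicative hash of the stage
#' label mixed into the seed, reduced modulo 2^31 - 1 (a valid R integer).
#'
#' @param seed Integer global seed.
#' @param stage Character stage label, e.g. `"cohort"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "cohort")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647 # 2^31 - 1, keeps products < 2^53 in double arithmetic
  x <- abs(as.numeric(seed)) %% m
  for (code in utf8ToInt(stage)) {
    x <- (x * 69069 + code) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

#' Bilinear image resize
#'
#' Resizes a grayscale image (matrix with rows = image rows) to the requested
#' height and width using bilinear interpolation.
#'
#' @param img Numeric matrix.
#' @param height,width Target dimensions in pixels.
#' @return A `height` x `width` numeric matrix.
#' @export
resize_bilinear <- function(img, height, width) {
  stopifnot(is.matrix(img), height >= 1, width >= 1)
  if (nrow(img) == height && ncol(img) == width) {
    return(img)
  }
  # EBImage's first array dimension corresponds to its `w` argument; our
  # matrices keep rows (image height) in dimension 1.
  out <- EBImage::resize(img, w = height, h = width, filter = "bilinear")
  matrix(as.numeric(out), nrow = height, ncol = width)
}

#' Gaussian blur
#'
#' Separable Gaussian convolution with reflected edges. Works on arbitrarily
#' small images (kernels are truncated at +-3 sigma).
#'
#' @param img Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma = 1) {
  stopifnot(is.matrix(img), sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_axis <- function(m, kern, radius) {
    n <- nrow(m)
    idx <- vapply(-radius:radius, function(d) {
      i <- seq_len(n) + d
      # reflect out-of-range indices back into [1, n]
      i <- ifelse(i < 1, 2 - i, i)
      as.integer(ifelse(i > n, 2 * n - i, i))
    }, integer(n))
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kern)) {
      out <- out + kern[j] * m[idx[, j], , drop = FALSE]
    }
    out
  }
  t(blur_axis(t(blur_axis(img, k, r)), k, r))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Shared argmax convention: ties go to the lowest class index (0-based).
argmax0 <- function(p) max.col(p, ties.method = "first") - 1L

assert_gray_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort(sprintf("`%s` must be a numeric matrix (grayscale image).", arg))
  }
  if (nrow(img) < 2 || ncol(img) < 2) {
    abort(sprintf("`%s` is degenerate: need at least 2x2 pixels.", arg))
  }
  invisible(img)
}

# Stable content hash used in manifests and determinism tests.
image_hash <- function(x) rlang::hash(round(as.numeric(x), 10))
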