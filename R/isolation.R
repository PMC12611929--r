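# Knee isolation: one bilateral radiograph -> two normalized 224x224 slices.
#
# Pipeline: standardize -> sharpen -> Otsu threshold -> morphological opening
# -> column-projection knee detection -> crop -> zero-pad to square -> resize
# -> divide by 255. Row correction (zeroing rows of identical pixels) is a
# fallback applied to the mask when detection fails on the opened mask.

#' Isolation parameters
#'
#' @param target_size Side of the standardized working image and of the final
#'   slice, in pixels.
#' @param sharpen_amount,sharpen_sigma Unsharp-mask strength and Gaussian
#'   sigma (pixels) used by [sharpen_image()].
#' @param kernel_size Side of the square structuring element for
#'   [morphological_opening()]. Chosen so that thin annotation text is removed
#'   while bone regions survive.
#' @param min_gap Column runs separated by fewer than this many empty columns
#'   are merged by [detect_knee_columns()].
#' @param min_run Column runs shorter than this are dropped.
#' @param crop_margin Rows added above/below the detected foreground when
#'   cropping.
#' @param crop_from Whether crops are taken from the `"sharpened"` or the
#'   plain `"standardized"` image.
#' @param midline_fallback If `TRUE`, a failed detection falls back to
#'   splitting at the widest empty column gap nearest the image midline.
#' @return A list of class `"isolation_params"`.
#' @export
isolation_params <- function(target_size = 224,
                             sharpen_amount = 1,
                             sharpen_sigma = 1,
                             kernel_size = 5,
                             min_gap = 5,
                             min_run = 10,
                             crop_margin = 2,
                             crop_from = c("sharpened", "standardized"),
                             midline_fallback = FALSE) {
  stopifnot(target_size >= 16, kernel_size >= 1, min_gap >= 1, min_run >= 1)
  structure(list(
    target_size = as.integer(target_size),
    sharpen_amount = sharpen_amount,
    sharpen_sigma = sharpen_sigma,
    kernel_size = as.integer(kernel_size),
    min_gap = as.integer(min_gap),
    min_run = as.integer(min_run),
    crop_margin = as.integer(crop_margin),
    crop_from = match.arg(crop_from),
    midline_fallback = midline_fallback
  ), class = "isolation_params")
}

#' Standardize a radiograph
#'
#' Resizes any-size grayscale or RGB input to a uniform square working size
#' and collapses color to luminance (0.299 R + 0.587 G + 0.114 B), preserving
#' the 8-bit intensity range.
#'
#' @param image Numeric matrix (grayscale) or `H x W x 3` array (RGB).
#' @param size Target side length in pixels (default 224).
#' @return A `size` x `size` numeric matrix.
#' @export
standardize_image <- function(image, size = 224) {
  if (is.array(image) && length(dim(image)) == 3) {
    if (dim(image)[3] != 3) abort("Color images must have exactly 3 channels.")
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  }
  if (!is.matrix(image)) abort("`image` must be a matrix or H x W x 3 array.")
  storage.mode(image) <- "double"
  assert_gray_image(image)
  resize_bilinear(image, size, size)
}

#' Sharpen an image by unsharp masking
#'
#' `img + amount * (img - gaussian_blur(img, sigma))`, clipped to `[0, 255]`.
#'
#' @param image Grayscale matrix.
#' @param amount Non-negative sharpening strength; 0 is the identity.
#' @param sigma Gaussian sigma of the blur, in pixels.
#' @return Sharpened matrix of the same shape.
#' @export
sharpen_image <- function(image, amount = 1, sigma = 1) {
  assert_gray_image(image)
  if (amount < 0) abort("`amount` must be >= 0.")
  if (amount == 0) return(image)
  clip(image + amount * (image - gaussian_blur(image, sigma)), 0, 255)
}

#' Otsu threshold
#'
#' Chooses the gray level maximizing the between-class variance of the 256-bin
#' intensity histogram; ties are broken toward the smallest maximizing
#' threshold. Foreground is strictly above the threshold.
#'
#' @param image Grayscale matrix with at least two distinct gray levels.
#' @return A list with `threshold` (gray level in 0..255) and `mask`
#'   (0/1 integer matrix, 1 = foreground).
#' @export
otsu_threshold <- function(image) {
  assert_gray_image(image)
  v <- clip(round(as.numeric(image)), 0, 255)
  if (length(unique(v)) < 2) abort("degenerate histogram: image has a single gray level.")
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)              # P(class0) for threshold t = level
  mu <- cumsum(p * levels)        # first moment up to t
  mu_t <- mu[256]
  # between-class variance for every candidate threshold t in 0..255
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_star <- levels[which.max(sigma_b)] # which.max takes the first (smallest) maximizer
  mask <- matrix(as.integer(image > t_star), nrow(image), ncol(image))
  list(threshold = t_star, mask = mask)
}

assert_binary_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    abort("`mask` must be a binary (0/1) matrix.")
  }
  invisible(mask)
}

# min/max filter over a square window via vectorized shifts; out-of-bounds
# pixels take `fill`.
shift_filter <- function(mask, k, op, fill) {
  h <- nrow(mask); w <- ncol(mask); r <- (k - 1L) %/% 2L
  out <- matrix(fill, h, w)
  pad <- matrix(fill, h + 2 * r, w + 2 * r)
  pad[r + seq_len(h), r + seq_len(w)] <- mask
  out <- NULL
  for (dr in 0:(k - 1)) {
    for (dc in 0:(k - 1)) {
      s <- pad[dr + seq_len(h), dc + seq_len(w)]
      out <- if (is.null(out)) s else op(out, s)
    }
  }
  out
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with the same structuring element (a square
#' of ones). Foreground components smaller than the element are removed;
#' kernel-open shapes are left unchanged.
#'
#' @param mask Binary 0/1 matrix.
#' @param kernel_size Side of the square structuring element (odd, >= 1).
#' @return Binary 0/1 integer matrix of the same shape.
#' @export
morphological_opening <- function(mask, kernel_size = 5) {
  assert_binary_mask(mask)
  k <- as.integer(kernel_size)
  if (k < 1 || k %% 2 == 0) abort("`kernel_size` must be odd and >= 1.")
  if (k == 1) return(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  # border handling: both erosion and dilation see background outside the image
  er <- shift_filter(mask == 1, k, `&`, fill = FALSE)
  di <- shift_filter(er, k, `|`, fill = FALSE)
  matrix(as.integer(di), nrow(mask), ncol(mask))
}

#' Zero rows of identical pixel values
#'
#' Pixel-correction fallback: every row whose pixels are all equal (to any
#' value) is replaced with zeros; all other rows are untouched. Idempotent.
#'
#' @param image Numeric matrix (grayscale image or mask).
#' @return Matrix of the same shape.
#' @export
fix_identical_rows <- function(image) {
  if (!is.matrix(image)) abort("`image` must be a matrix.")
  rng <- matrixStats_rowrange(image)
  constant <- rng[, 1] == rng[, 2]
  image[constant, ] <- 0
  image
}

# row-wise min/max without a matrixStats dependency
matrixStats_rowrange <- function(m) {
  cbind(do.call(pmin, asplit(m, 2)), do.call(pmax, asplit(m, 2)))
}

#' Detect the two knee column intervals
#'
#' Computes per-column foreground counts, takes maximal runs of columns with
#' a positive count, merges runs separated by fewer than `min_gap` empty
#' columns, drops runs shorter than `min_run`, and returns the two
#' largest-area runs ordered left to right.
#'
#' @param mask Binary 0/1 matrix (typically the opened Otsu mask).
#' @param min_gap,min_run Run merging / filtering parameters (columns).
#' @return A list of two `c(start, end)` integer vectors, 0-based half-open
#'   column intervals, left knee first.
#' @export
detect_knee_columns <- function(mask, min_gap = 5, min_run = 10) {
  assert_binary_mask(mask)
  counts <- colSums(mask)
  nz <- counts > 0
  if (!any(nz)) {
    abort("knee separation failed: mask has no foreground columns.",
          class = "kneegrade_separation_error", runs = list())
  }
  r <- rle(nz)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values]) # 1-based incl.
  # merge runs separated by < min_gap empty columns
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1L
      if (gap < min_gap) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start + 1L >= min_run, , drop = FALSE]
  run_list <- lapply(seq_len(nrow(merged)), function(i) {
    c(start = merged$start[i] - 1L, end = merged$end[i])
  })
  if (nrow(merged) < 2) {
    abort(sprintf("knee separation failed: %d qualifying column run(s), need 2.",
                  nrow(merged)),
          class = "kneegrade_separation_error", runs = run_list)
  }
  area <- vapply(seq_len(nrow(merged)), function(i) {
    sum(counts[merged$start[i]:merged$end[i]])
  }, numeric(1))
  keep <- sort(order(area, decreasing = TRUE)[1:2])
  run_list[keep]
}

#' Crop the two knees from a standardized image
#'
#' For each detected column interval, crops the image to those columns and to
#' the row span of foreground pixels within the interval, extended by
#' `margin` rows and clipped to the image bounds.
#'
#' @param image Grayscale matrix (standardized, optionally sharpened).
#' @param intervals List of two 0-based half-open `c(start, end)` column
#'   intervals, as returned by [detect_knee_columns()].
#' @param mask Binary foreground mask aligned with `image`.
#' @param margin Extra rows above and below the foreground span.
#' @return A list of two crops, each a list with `pixels` (matrix), `side`
#'   (`"left"`/`"right"`), `cols` and `rows` (0-based half-open source spans).
#' @export
crop_knees <- function(image, intervals, mask, margin = 2) {
  assert_gray_image(image)
  stopifnot(length(intervals) == 2)
  sides <- c("left", "right")
  lapply(1:2, function(i) {
    iv <- intervals[[i]]
    if (iv[["end"]] - iv[["start"]] < 2) {
      abort("degenerate column interval: need at least 2 columns.")
    }
    cols <- (iv[["start"]] + 1L):iv[["end"]]
    fg_rows <- which(rowSums(mask[, cols, drop = FALSE]) > 0)
    if (length(fg_rows) == 0) abort("empty row range inside column interval.")
    r0 <- max(1L, min(fg_rows) - margin)
    r1 <- min(nrow(image), max(fg_rows) + margin)
    list(pixels = image[r0:r1, cols, drop = FALSE],
         side = sides[i],
         cols = c(start = iv[["start"]], end = iv[["end"]]),
         rows = c(start = r0 - 1L, end = r1))
  })
}

#' Zero-pad a crop to a square and normalize to [0, 1]
#'
#' Pads the shorter dimension symmetrically with zeros (odd remainders put
#' the extra row/column at the bottom/right), so the aspect ratio of the
#' content is preserved, then resizes to `size` x `size` and divides by 255.
#'
#' @param crop Non-empty grayscale matrix with 8-bit intensities.
#' @param size Final slice side length (default 224).
#' @return A `size` x `size` matrix with values in `[0, 1]`.
#' @export
pad_and_normalize <- function(crop, size = 224) {
  if (!is.matrix(crop) || length(crop) == 0) abort("`crop` must be a non-empty matrix.")
  h <- nrow(crop); w <- ncol(crop)
  if (h != w) {
    d <- abs(h - w)
    pre <- d %/% 2L
    post <- d - pre
    if (h < w) {
      crop <- rbind(matrix(0, pre, w), crop, matrix(0, post, w))
    } else {
      crop <- cbind(matrix(0, h, pre), crop, matrix(0, h, post))
    }
  }
  clip(resize_bilinear(crop, size, size) / 255, 0, 1)
}

# Midline fallback: split at the widest empty-column gap nearest the centre.
midline_split <- function(mask) {
  counts <- colSums(mask)
  w <- length(counts)
  r <- rle(counts == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  zruns <- data.frame(start = starts[r$values], end = ends[r$values])
  zruns <- zruns[zruns$start > 1 & zruns$end < w, , drop = FALSE]
  if (nrow(zruns) == 0) {
    split_at <- w %/% 2L
  } else {
    len <- zruns$end - zruns$start + 1L
    mid <- (zruns$start + zruns$end) / 2
    score <- len - abs(mid - w / 2) / w # prefer wide gaps near the midline
    i <- which.max(score)
    split_at <- as.integer(round(mid[i]))
  }
  list(c(start = 0L, end = split_at), c(start = split_at, end = w))
}

#' Isolate both knees from one bilateral radiograph
#'
#' Runs the full isolation pipeline on a single image: standardize ->
#' sharpen -> Otsu threshold -> morphological opening -> column detection
#' (with row-correction retry, and an optional midline fallback) -> crop ->
#' zero-pad -> normalize.
#'
#' @param image Grayscale matrix or RGB array of any size.
#' @param params An [isolation_params()].
#' @return A list with `slices` (list of two `size` x `size` matrices in
#'   `[0, 1]`, left then right), `intervals` (detected 0-based column
#'   intervals on the standardized image), `crops` (raw crop metadata),
#'   `threshold` (Otsu gray level) and `mask` (opened binary mask).
#' @export
isolate_knees <- function(image, params = isolation_params()) {
  std <- standardize_image(image, params$target_size)
  sharp <- sharpen_image(std, params$sharpen_amount, params$sharpen_sigma)
  ot <- otsu_threshold(sharp)
  opened <- morphological_opening(ot$mask, params$kernel_size)
  mask <- opened
  intervals <- tryCatch(
    detect_knee_columns(mask, params$min_gap, params$min_run),
    kneegrade_separation_error = function(e) {
      mask <<- fix_identical_rows(opened)
      tryCatch(
        detect_knee_columns(mask, params$min_gap, params$min_run),
        kneegrade_separation_error = function(e2) {
          if (params$midline_fallback) midline_split(mask) else cnd_signal(e2)
        }
      )
    }
  )
  src <- if (params$crop_from == "sharpened") sharp else std
  crops <- crop_knees(src, intervals, mask, params$crop_margin)
  slices <- lapply(crops, function(cr) pad_and_normalize(cr$pixels, params$target_size))
  list(slices = slices, intervals = intervals, crops = crops,
       threshold = ot$threshold, mask = mask)
}

#' Isolate every knee in a cohort
#'
#' Maps [isolate_knees()] over a cohort tibble and returns one row per knee.
#' Metadata columns (`set` from [patient_split()], pain flags, age, sex) are
#' carried through; each slice inherits its patient ID and per-side grade.
#'
#' @param cohort Tibble from [generate_cohort()] (optionally after
#'   [patient_split()]).
#' @param params An [isolation_params()].
#' @return A tibble with columns `patient_id`, `side`, `grade`, `pain`,
#'   `pixels` (list-column of 224 x 224 matrices in `[0, 1]`), `source_cols`
#'   and `source_rows` (list-columns of 0-based half-open spans), plus any
#'   carried metadata.
#' @export
#' @examples
#' cohort <- generate_cohort(2, seed = 1)
#' slices <- isolate_cohort(cohort)
#' nrow(slices) # two knees per radiograph
isolate_cohort <- function(cohort, params = isolation_params()) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1)
  extra <- intersect(c("set", "age", "sex"), names(cohort))
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    iso <- tryCatch(
      isolate_knees(cohort$image[[i]], params),
      kneegrade_separation_error = function(e) {
        abort(sprintf("knee separation failed for record %s: %s",
                      cohort$patient_id[i], conditionMessage(e)),
              class = "kneegrade_separation_error")
      }
    )
    grades <- c(cohort$grade_left[i], cohort$grade_right[i])
    pains <- if (all(c("pain_left", "pain_right") %in% names(cohort))) {
      c(cohort$pain_left[i], cohort$pain_right[i])
    } else c(NA, NA)
    out <- tibble(
      patient_id = cohort$patient_id[i],
      side = c("left", "right"),
      grade = as.integer(grades),
      pain = pains,
      pixels = iso$slices,
      source_cols = lapply(iso$crops, `[[`, "cols"),
      source_rows = lapply(iso$crops, `[[`, "rows")
    )
    for (col in extra) out[[col]] <- cohort[[col]][i]
    out
  })
  out <- bind_rows(rows)
  stopifnot(all(vapply(out$pixels, function(p) {
    all(dim(p) == params$target_size) && min(p) >= 0 && max(p) <= 1
  }, logical(1))))
  out
}

#' Column-interval Jaccard index
#'
#' Overlap-over-union of two 0-based half-open column intervals; used to
#' compare detected knee intervals with phantom ground truth.
#'
#' @param a,b Vectors with elements `start` and `end` (or `col_start` /
#'   `col_end`), 0-based half-open.
#' @return Jaccard index in `[0, 1]`.
#' @export
column_jaccard <- function(a, b) {
  pick <- function(x, n1, n2) if (n1 %in% names(x)) x[[n1]] else x[[n2]]
  a0 <- pick(a, "start", "col_start"); a1 <- pick(a, "end", "col_end")
  b0 <- pick(b, "start", "col_start"); b1 <- pick(b, "end", "col_end")
  inter <- max(0, min(a1, b1) - max(a0, b0))
  union <- max(a1, b1) - min(a0, b0)
  if (union <= 0) return(0)
  inter / union
}
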