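# Patient-level leakage-free splitting and training-set augmentation.
#
# The test set is held out at the patient level before any augmentation; the
# validation set is carved out of the augmented training pool at slice level
# (the study protocol), with a stricter by-patient option available.

#' Augmentation configuration
#'
#' Ranges follow the study protocol: rotation within +-30 degrees, isotropic
#' zoom in 0.8-1.2, shifts up to 10% of the image size per axis, shear within
#' +-20 degrees, and horizontal flipping.
#'
#' @param rotation_deg Half-range of the uniform rotation draw, degrees.
#' @param zoom_range Length-2 `(low, high)` isotropic zoom factors.
#' @param shift_frac Maximum shift as a fraction of the image side, per axis.
#' @param shear_deg Half-range of the uniform shear draw, degrees.
#' @param hflip Apply horizontal flips with probability 0.5.
#' @param copies_per_image Augmented copies generated per training slice
#'   (the original is always kept as well).
#' @return A list of class `"augment_config"`.
#' @export
augment_config <- function(rotation_deg = 30,
                           zoom_range = c(0.8, 1.2),
                           shift_frac = 0.10,
                           shear_deg = 20,
                           hflip = TRUE,
                           copies_per_image = 5) {
  stopifnot(rotation_deg >= 0, shift_frac >= 0, shear_deg >= 0,
            copies_per_image >= 0)
  if (length(zoom_range) != 2 || zoom_range[1] > zoom_range[2] || zoom_range[1] <= 0) {
    abort("zoom_range must be (low, high) with 0 < low <= high.")
  }
  structure(list(
    rotation_deg = rotation_deg, zoom_range = zoom_range,
    shift_frac = shift_frac, shear_deg = shear_deg,
    hflip = isTRUE(hflip), copies_per_image = as.integer(copies_per_image)
  ), class = "augment_config")
}

#' Split a cohort by patient into train and test
#'
#' Patients are shuffled under the seed and `ceiling(test_frac * n)` of them
#' form the test set -- the rounding rule consistent with 301 patients at 20%
#' giving 61 test patients. When every stratum (a patient's maximum knee
#' grade) has at least two patients the split is stratified; otherwise it
#' falls back to an unstratified split with a warning. All knees of a patient
#' land on the same side of the boundary.
#'
#' @param cohort Cohort tibble from [generate_cohort()] (needs `patient_id`,
#'   `grade_left`, `grade_right`).
#' @param test_frac Test fraction in (0, 1).
#' @param seed Optional integer seed.
#' @param stratify Stratify by each patient's maximum knee grade.
#' @return The cohort with an added `set` column (`"train"` / `"test"`).
#' @export
#' @examples
#' cohort <- generate_cohort(10, seed = 1)
#' table(patient_split(cohort, 0.2, seed = 1)$set)
patient_split <- function(cohort, test_frac = 0.2, seed = NULL, stratify = TRUE) {
  stopifnot(is.data.frame(cohort))
  if (!(test_frac > 0 && test_frac < 1)) abort("test_frac must be in (0, 1).")
  n <- nrow(cohort)
  if (n < 2) abort("Need at least 2 patients to split.")
  if (anyDuplicated(cohort$patient_id)) abort("patient_id values must be unique.")
  if (!is.null(seed)) withr::local_seed(seed)

  n_test <- as.integer(ceiling(test_frac * n))
  stratum <- pmax(cohort$grade_left, cohort$grade_right)
  tab <- table(stratum)
  use_strat <- stratify && all(tab >= 2)
  if (stratify && !use_strat) {
    warn("Some strata have fewer than 2 patients; splitting without stratification.")
  }
  test_idx <- if (use_strat) {
    # proportional allocation with largest-remainder rounding to hit n_test exactly
    share <- n_test * as.numeric(tab) / n
    base <- floor(share)
    rem <- n_test - sum(base)
    if (rem > 0) {
      extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    base <- pmin(base, as.numeric(tab)) # never exceed a stratum
    deficit <- n_test - sum(base)
    unlist(lapply(seq_along(tab), function(k) {
      idx <- which(stratum == as.integer(names(tab)[k]))
      sample(idx, base[k])
    })) |>
      (\(ix) if (deficit > 0) c(ix, sample(setdiff(seq_len(n), ix), deficit)) else ix)()
  } else {
    sample(seq_len(n), n_test)
  }
  cohort$set <- ifelse(seq_len(n) %in% test_idx, "test", "train")
  cohort
}

# 2x2 rotation/zoom/shear/flip composition; angles in degrees.
augment_matrix <- function(rot, zoom, shear, flip) {
  th <- rot * pi / 180
  sh <- shear * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Z <- diag(c(zoom, zoom))
  S <- matrix(c(1, 0, tan(sh), 1), 2, 2) # shear along columns
  f <- if (flip) diag(c(1, -1)) else diag(2) # flip mirrors columns (horizontal)
  f %*% S %*% Z %*% R
}

# Bilinear sampling of `img` at transformed coordinates: output pixel p maps
# to source M^-1 (p - center - t) + center; outside pixels read as 0.
affine_warp <- function(img, M, t_rows = 0, t_cols = 0) {
  h <- nrow(img); w <- ncol(img)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  Minv <- solve(M)
  grid_r <- rep(seq_len(h), times = w) - cr - t_rows
  grid_c <- rep(seq_len(w), each = h) - cc - t_cols
  src_r <- Minv[1, 1] * grid_r + Minv[1, 2] * grid_c + cr
  src_c <- Minv[2, 1] * grid_r + Minv[2, 2] * grid_c + cc
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    fr * fc * val(r0 + 1, c0 + 1)
  matrix(out, h, w)
}

#' Randomly augment one knee slice
#'
#' Applies, with independent uniform draws: rotation, isotropic zoom,
#' per-axis translation, shear, and (with probability 0.5) a horizontal
#' flip -- composed into a single affine transform about the image center and
#' resampled bilinearly with zero fill. The label, side and patient of a
#' slice are never touched.
#'
#' @param pixels `224 x 224` matrix in `[0, 1]`.
#' @param cfg An [augment_config()].
#' @param seed Optional seed for the draws.
#' @return A matrix of the same shape with values in `[0, 1]`.
#' @export
augment_slice <- function(pixels, cfg = augment_config(), seed = NULL) {
  assert_gray_image(pixels, "pixels")
  if (!is.null(seed)) withr::local_seed(seed)
  rot <- runif(1, -cfg$rotation_deg, cfg$rotation_deg)
  zoom <- runif(1, cfg$zoom_range[1], cfg$zoom_range[2])
  sh <- runif(1, -cfg$shear_deg, cfg$shear_deg)
  tr <- runif(2, -cfg$shift_frac, cfg$shift_frac) * dim(pixels)
  flip <- cfg$hflip && runif(1) < 0.5
  M <- augment_matrix(rot, zoom, sh, flip)
  if (all(M == diag(2)) && all(tr == 0)) return(pixels)
  clip(affine_warp(pixels, M, tr[1], tr[2]), 0, 1)
}

#' Build augmented train / validation / test slice sets
#'
#' Every training slice contributes its original plus `copies_per_image`
#' augmented copies; the pooled result is split 90/10 into train and
#' validation at slice level (the study protocol; `val_by_patient = TRUE`
#' gives the stricter patient-level variant). Test slices pass through
#' untouched.
#'
#' @param slices Slice tibble from [isolate_cohort()] carrying a `set`
#'   column from [patient_split()].
#' @param cfg An [augment_config()].
#' @param val_frac Validation fraction of the augmented pool.
#' @param seed Optional integer seed.
#' @param val_by_patient Carve validation out by patient instead of by slice.
#' @return A list of class `"cohort_split"` with tibbles `train`, `val`,
#'   `test`; augmented rows are flagged in the `augmented` column.
#' @export
build_sets <- function(slices, cfg = augment_config(), val_frac = 0.1,
                       seed = NULL, val_by_patient = FALSE) {
  stopifnot(is.data.frame(slices), "set" %in% names(slices))
  if (!is.null(seed)) withr::local_seed(seed)
  train_sl <- dplyr::filter(slices, .data$set == "train")
  test_sl <- dplyr::filter(slices, .data$set == "test")
  if (nrow(train_sl) == 0) abort("empty training pool: no slices with set == \"train\".")

  train_sl$augmented <- FALSE
  pool <- list(train_sl)
  for (k in seq_len(cfg$copies_per_image)) {
    copy <- train_sl
    copy$pixels <- lapply(train_sl$pixels, augment_slice, cfg = cfg)
    copy$augmented <- TRUE
    pool[[k + 1]] <- copy
  }
  pool <- bind_rows(pool)

  n_val <- floor(val_frac * nrow(pool))
  if (val_by_patient) {
    pats <- unique(pool$patient_id)
    val_pats <- sample(pats, max(1, round(val_frac * length(pats))))
    val_idx <- which(pool$patient_id %in% val_pats)
  } else {
    val_idx <- sample(nrow(pool), n_val)
  }
  val <- pool[val_idx, , drop = FALSE]
  train <- pool[setdiff(seq_len(nrow(pool)), val_idx), , drop = FALSE]
  if (nrow(test_sl)) test_sl$augmented <- FALSE

  split <- structure(list(train = as_tibble(train), val = as_tibble(val),
                          test = as_tibble(test_sl)),
                     class = "cohort_split")
  assert_no_leakage(split)
  split
}

# Train/val patients must never appear in the test set.
assert_no_leakage <- function(split) {
  trainval <- unique(c(split$train$patient_id, split$val$patient_id))
  if (length(intersect(trainval, unique(split$test$patient_id)))) {
    abort("patient leakage: a patient appears on both sides of the train/test boundary.")
  }
  invisible(split)
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("<cohort_split>\n")
  for (s in c("train", "val", "test")) {
    cat(sprintf("  %-5s: %4d slices, %3d patients, %d augmented\n", s,
                nrow(x[[s]]), length(unique(x[[s]]$patient_id)),
                sum(x[[s]]$augmented %||% 0)))
  }
  invisible(x)
}

#' @export
glance.cohort_split <- function(x, ...) {
  tibble(
    n_train = nrow(x$train), n_val = nrow(x$val), n_test = nrow(x$test),
    n_train_patients = length(unique(c(x$train$patient_id, x$val$patient_id))),
    n_test_patients = length(unique(x$test$patient_id))
  )
}
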