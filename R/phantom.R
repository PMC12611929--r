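# Synthetic bilateral knee radiograph phantoms.
#
# The phantom carries exactly the image cues that drive Kellgren-Lawrence
# grading on real films -- a joint-space gap that narrows with grade and
# marginal osteophytes that multiply with grade -- plus the nuisance features
# an isolation pipeline must survive: a text-like annotation block in the
# upper-left corner and per-image size variation. Grades 0 and 1 are rendered
# from identical geometry; their label difference is a latent pain flag only.

#' Default per-grade class mix
#'
#' Per-grade probabilities proportional to the cohort composition reported for
#' the clinical population this generator emulates (grade 0:4 counts
#' 18/67/105/126/86). The published counts sum to 402 rather than the number
#' of patients, so they are used as proportions only and never asserted.
#'
#' @return A numeric vector of 5 probabilities summing to 1, named "0".."4".
#' @export
kl_class_mix <- function() {
  setNames(c(18, 67, 105, 126, 86) / 402, as.character(0:4))
}

#' Phantom radiograph configuration
#'
#' @param image_height,image_width Nominal image size in pixels before
#'   per-image jitter.
#' @param bone_intensity Gray level of bone regions (0-255).
#' @param background_mean Mean gray level of soft-tissue background.
#' @param noise_sd Standard deviation of additive Gaussian noise (gray levels).
#' @param joint_gap_by_grade Named map KL grade -> joint-space gap height in
#'   pixels. Grades 0 and 1 must be equal (their radiographic appearance is
#'   identical) and the gap must not increase from grade 1 to 4 (joint-space
#'   narrowing).
#' @param osteophyte_count_by_grade Named map KL grade -> number of marginal
#'   osteophytes per knee. Grades 0 and 1 must be equal.
#' @param annotation_block `(height, width)` in pixels of the text-like
#'   annotation region drawn in the upper-left corner.
#' @param size_jitter Fractional half-range of per-image height/width
#'   variation, e.g. 0.15 for +-15%.
#' @return A validated list of class `"phantom_config"`.
#' @export
phantom_config <- function(image_height = 400,
                           image_width = 600,
                           bone_intensity = 200,
                           background_mean = 15,
                           noise_sd = 5,
                           joint_gap_by_grade = c("0" = 12, "1" = 12, "2" = 8,
                                                  "3" = 4, "4" = 1),
                           osteophyte_count_by_grade = c("0" = 0, "1" = 0,
                                                         "2" = 1, "3" = 2,
                                                         "4" = 4),
                           annotation_block = c(12, 60),
                           size_jitter = 0.15) {
  gap <- joint_gap_by_grade[as.character(0:4)]
  ost <- osteophyte_count_by_grade[as.character(0:4)]
  if (anyNA(gap) || anyNA(ost)) {
    abort("joint_gap_by_grade and osteophyte_count_by_grade must name grades \"0\"..\"4\".")
  }
  if (gap[["0"]] != gap[["1"]] || ost[["0"]] != ost[["1"]]) {
    abort("Grades 0 and 1 must be image-identical: equal gap and osteophyte count.")
  }
  if (any(diff(gap[as.character(1:4)]) > 0)) {
    abort("joint_gap_by_grade must be non-increasing from grade 1 to 4 (joint-space narrowing).")
  }
  if (!(background_mean >= 0 && background_mean < bone_intensity && bone_intensity <= 255)) {
    abort("Need 0 <= background_mean < bone_intensity <= 255.")
  }
  if (size_jitter < 0 || size_jitter >= 1) abort("size_jitter must be in [0, 1).")
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    bone_intensity = bone_intensity,
    background_mean = background_mean,
    noise_sd = noise_sd,
    joint_gap_by_grade = gap,
    osteophyte_count_by_grade = ost,
    annotation_block = as.integer(annotation_block),
    size_jitter = size_jitter
  ), class = "phantom_config")
}

check_grade <- function(grade, arg) {
  if (length(grade) != 1 || is.na(grade) || grade %% 1 != 0 || grade < 0 || grade > 4) {
    abort(sprintf("`%s` must be a single KL grade in 0..4, got %s.",
                  arg, deparse(grade)))
  }
  as.integer(grade)
}

# Fill an ellipse into the bone mask; clipped to image bounds.
fill_ellipse <- function(mask, center_r, center_c, ar, ac) {
  rr <- clip(seq(floor(center_r - ar), ceiling(center_r + ar)), 1, nrow(mask))
  cc <- clip(seq(floor(center_c - ac), ceiling(center_c + ac)), 1, ncol(mask))
  rr <- unique(rr); cc <- unique(cc)
  d <- outer((rr - center_r)^2 / ar^2, (cc - center_c)^2 / ac^2, `+`)
  sub <- mask[rr, cc, drop = FALSE]
  sub[d <= 1] <- TRUE
  mask[rr, cc] <- sub
  mask
}

# One knee: femur block above tibia block separated by `gap` background rows,
# with `n_ost` bright marginal osteophytes at the joint margins.
draw_knee <- function(h, w, c0, c1, gap, n_ost) {
  mask <- matrix(FALSE, h, w)
  r_top <- round(0.15 * h)
  r_bot <- round(0.90 * h)
  gap_center <- round(0.52 * h)
  gs <- gap_center - floor(gap / 2) # first background row of the joint space
  mask[r_top:(gs - 1), c0:c1] <- TRUE          # femur
  mask[(gs + gap):r_bot, c0:c1] <- TRUE        # tibia
  if (n_ost > 0) {
    # marginal osteophytes: femur-left, tibia-right, femur-right, tibia-left
    centers <- list(c(gs - 2, c0), c(gs + gap + 1, c1),
                    c(gs - 2, c1), c(gs + gap + 1, c0))
    for (k in seq_len(min(n_ost, 4))) {
      ct <- centers[[k]]
      mask <- fill_ellipse(mask, ct[1], ct[2], ar = 4, ac = 7)
    }
  }
  list(mask = mask, gap_rows = gs:(gs + gap - 1))
}

# Text-like annotation strokes (1-2 px wide) in the upper-left corner. Strokes
# are kept thinner than any reasonable opening kernel so segmentation removes
# them, mirroring the faint patient-detail text on real films.
draw_annotation <- function(h, w, block) {
  mask <- matrix(FALSE, h, w)
  bh <- min(block[1], h - 4)
  bw <- min(block[2], w - 6)
  r0 <- 4; c0 <- 6
  n_strokes <- max(3L, bw %/% 8L)
  cols <- sort(sample(seq(c0, c0 + bw - 2), n_strokes))
  for (cc in cols) {
    wd <- sample(1:2, 1)
    mask[r0:(r0 + bh - 2), cc:(cc + wd - 1)] <- TRUE
  }
  mask[r0 + bh - 1, c0:(c0 + bw - 1)] <- TRUE # 1-px baseline
  mask
}

#' Generate one synthetic bilateral knee radiograph
#'
#' Renders a phantom film containing two knees (femur block above tibia block,
#' separated by the grade's joint-space gap, with grade-dependent marginal
#' osteophytes), a text-like annotation block in the upper-left corner, and
#' additive Gaussian noise. The ground-truth bounding box of each knee's bone
#' pixels is recorded in 0-based half-open coordinates.
#'
#' @param grade_left,grade_right KL grades (0-4) of the left and right knee
#'   (left = smaller image columns).
#' @param cfg A [phantom_config()].
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @param patient_id Patient identifier string.
#' @return A one-row tibble with columns `patient_id`, `age`, `sex`,
#'   `grade_left`, `grade_right`, `pain_left`, `pain_right`, `image`
#'   (list-column holding an integer matrix of 8-bit gray levels) and
#'   `truth_left` / `truth_right` (list-columns holding named vectors
#'   `col_start`, `col_end`, `row_start`, `row_end`, 0-based half-open).
#' @export
#' @examples
#' rec <- generate_phantom(2, 3, seed = 1)
#' dim(rec$image[[1]])
generate_phantom <- function(grade_left, grade_right, cfg = phantom_config(),
                             seed = NULL, patient_id = "P0001") {
  grade_left <- check_grade(grade_left, "grade_left")
  grade_right <- check_grade(grade_right, "grade_right")
  stopifnot(inherits(cfg, "phantom_config"))
  if (!is.null(seed)) withr::local_seed(seed)

  jit <- function(n) as.integer(round(n * runif(1, 1 - cfg$size_jitter, 1 + cfg$size_jitter)))
  h <- jit(cfg$image_height)
  w <- jit(cfg$image_width)

  # per-knee horizontal jitter, keeping the two knees column-disjoint
  dx <- as.integer(round(runif(2, -0.02, 0.02) * w))
  l0 <- max(2L, round(0.08 * w) + dx[1]); l1 <- round(0.38 * w) + dx[1]
  r0 <- round(0.62 * w) + dx[2]; r1 <- min(w - 1L, round(0.92 * w) + dx[2])

  gapL <- cfg$joint_gap_by_grade[[as.character(grade_left)]]
  gapR <- cfg$joint_gap_by_grade[[as.character(grade_right)]]
  ostL <- cfg$osteophyte_count_by_grade[[as.character(grade_left)]]
  ostR <- cfg$osteophyte_count_by_grade[[as.character(grade_right)]]

  left <- draw_knee(h, w, l0, l1, gapL, ostL)
  right <- draw_knee(h, w, r0, r1, gapR, ostR)
  ann <- draw_annotation(h, w, cfg$annotation_block)

  img <- matrix(cfg$background_mean, h, w)
  img[left$mask | right$mask] <- cfg$bone_intensity
  img[ann] <- 240

  age <- runif(1, 40, 80)
  sex <- sample(c("F", "M"), 1, prob = c(162, 139))
  img <- img + matrix(rnorm(h * w, 0, cfg$noise_sd), h, w)
  img <- round(clip(img, 0, 255))
  storage.mode(img) <- "integer"

  box <- function(mask) {
    rr <- range(which(rowSums(mask) > 0))
    cc <- range(which(colSums(mask) > 0))
    c(col_start = cc[1] - 1L, col_end = cc[2], row_start = rr[1] - 1L, row_end = rr[2])
  }

  tibble(
    patient_id = patient_id,
    age = age,
    sex = sex,
    grade_left = grade_left,
    grade_right = grade_right,
    pain_left = grade_left >= 1,  # grade 1 = pain with normal film; >=2 symptomatic
    pain_right = grade_right >= 1,
    image = list(img),
    truth_left = list(box(left$mask)),
    truth_right = list(box(right$mask))
  )
}

#' Generate a cohort of phantom radiographs
#'
#' @param n_patients Number of patients (one bilateral radiograph each).
#' @param class_mix Per-grade probabilities for grades 0..4; must sum to 1.
#'   Defaults to [kl_class_mix()].
#' @param cfg A [phantom_config()].
#' @param seed Integer seed; the cohort is bit-reproducible given the seed.
#' @return A tibble with one row per patient (see [generate_phantom()] for
#'   columns). Per-knee grades are drawn i.i.d. from `class_mix`; ages are
#'   uniform on `[40, 80]` (the emulated cohort's inclusion criterion).
#' @export
#' @examples
#' cohort <- generate_cohort(5, seed = 1)
#' cohort$grade_left
generate_cohort <- function(n_patients, class_mix = kl_class_mix(),
                            cfg = phantom_config(), seed = NULL) {
  if (n_patients < 1) abort("n_patients must be >= 1.")
  if (length(class_mix) != 5 || !is.numeric(class_mix)) {
    abort("class_mix must be 5 per-grade probabilities.")
  }
  bad <- which(class_mix < 0 | class_mix > 1)
  if (length(bad)) {
    abort(sprintf("class_mix[%d] = %g is not a probability in [0, 1].",
                  bad[1], class_mix[bad[1]]))
  }
  if (abs(sum(class_mix) - 1) > 1e-9) {
    abort(sprintf("class_mix must sum to 1 (got %.12f).", sum(class_mix)))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  grades <- matrix(sample(0:4, 2 * n_patients, replace = TRUE, prob = class_mix),
                   ncol = 2)
  ids <- sprintf("P%04d", seq_len(n_patients))
  bind_rows(lapply(seq_len(n_patients), function(i) {
    generate_phantom(grades[i, 1], grades[i, 2], cfg = cfg,
                     patient_id = ids[i])
  }))
}

#' Measure the joint-space gap of a phantom knee
#'
#' Counts, for each column in the central half of the knee's truth box, the
#' background rows between the femur and tibia bone runs, and returns the
#' mean. Used to validate the generator's grade-dependent geometry.
#'
#' @param image Integer matrix (the phantom image).
#' @param truth_box Named vector `col_start`, `col_end`, `row_start`,
#'   `row_end` (0-based half-open) as produced by [generate_phantom()].
#' @param bone_thresh Gray level above which a pixel counts as bone; defaults
#'   to halfway between the default background and bone intensities.
#' @return Mean gap height in pixels across the sampled columns.
#' @export
measure_joint_gap <- function(image, truth_box, bone_thresh = 107) {
  cs <- truth_box[["col_start"]] + 1L
  ce <- truth_box[["col_end"]]
  rs <- truth_box[["row_start"]] + 1L
  re <- truth_box[["row_end"]]
  width <- ce - cs + 1L
  cols <- seq(cs + round(width * 0.25), ce - round(width * 0.25))
  gaps <- vapply(cols, function(cc) {
    bone <- which(image[rs:re, cc] >= bone_thresh)
    if (length(bone) < 2) return(NA_real_)
    runs <- rle(seq(min(bone), max(bone)) %in% bone)
    sum(runs$lengths[!runs$values])
  }, numeric(1))
  mean(gaps, na.rm = TRUE)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  nominal size : %d x %d (+-%.0f%%)\n", x$image_height,
              x$image_width, 100 * x$size_jitter))
  cat(sprintf("  intensities  : bone %g, background %g, noise sd %g\n",
              x$bone_intensity, x$background_mean, x$noise_sd))
  cat("  gap by grade :", paste(x$joint_gap_by_grade, collapse = "/"), "px\n")
  cat("  osteophytes  :", paste(x$osteophyte_count_by_grade, collapse = "/"), "\n")
  invisible(x)
}
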