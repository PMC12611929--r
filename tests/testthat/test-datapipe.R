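test_that("patient split honors the ceiling rule and keeps patients intact", {
  cohort <- generate_cohort(10, seed = 5)
  sp <- patient_split(cohort, 0.2, seed = 1, stratify = FALSE)
  expect_equal(sum(sp$set == "test"), 2)
  expect_equal(sum(sp$set == "train"), 8)
  expect_setequal(unique(sp$set), c("train", "test"))
  # determinism and seed sensitivity
  sp2 <- patient_split(cohort, 0.2, seed = 1, stratify = FALSE)
  expect_identical(sp$set, sp2$set)
  cohort12 <- generate_cohort(12, seed = 6)
  base <- patient_split(cohort12, 0.25, seed = 1, stratify = FALSE)$set
  differs <- vapply(2:21, function(s) {
    !identical(patient_split(cohort12, 0.25, seed = s, stratify = FALSE)$set,
               base)
  }, logical(1))
  expect_true(any(differs))
  expect_error(patient_split(cohort[1, ], 0.2), "2 patients")
  expect_error(patient_split(cohort, 1.2), "test_frac")
})

test_that("splitting warns and falls back when a stratum is a singleton", {
  cohort <- generate_cohort(9, class_mix = c(0, 0, 0.5, 0.5, 0), seed = 3)
  # force one singleton stratum
  cohort$grade_left[1] <- 0L
  cohort$grade_right[1] <- 0L
  cohort$grade_left[-1] <- 4L
  expect_warning(patient_split(cohort, 0.3, seed = 2), "strata")
})

test_that("an all-zero augmentation configuration is the identity", {
  cfg <- augment_config(rotation_deg = 0, zoom_range = c(1, 1), shift_frac = 0,
                        shear_deg = 0, hflip = FALSE)
  px <- matrix(runif(224 * 224), 224)
  expect_identical(augment_slice(px, cfg, seed = 1), px)
})

test_that("augmented slices keep shape and range", {
  px <- matrix(runif(224 * 224), 224)
  for (s in 1:5) {
    out <- augment_slice(px, augment_config(), seed = s)
    expect_equal(dim(out), c(224, 224))
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
  }
})

test_that("rotating by 90 degrees and back recovers the image center", {
  set.seed(8)
  img <- gaussian_blur(matrix(runif(224 * 224), 224), 3)
  M90 <- kneegrade:::augment_matrix(90, 1, 0, FALSE)
  Mm90 <- kneegrade:::augment_matrix(-90, 1, 0, FALSE)
  there <- kneegrade:::affine_warp(img, M90)
  back <- kneegrade:::affine_warp(there, Mm90)
  ctr <- 57:168 # central 112 x 112 window
  expect_lt(mean(abs(back[ctr, ctr] - img[ctr, ctr])), 0.02)
})

test_that("build_sets follows the augment-then-split-90/10 protocol", {
  set.seed(2)
  slices <- rbind(random_slices(20, set = "train", prefix = "A"),
                  random_slices(6, set = "test", prefix = "B"))
  cfg <- augment_config(copies_per_image = 5)
  sets <- build_sets(slices, cfg, val_frac = 0.1, seed = 1)
  expect_equal(nrow(sets$train) + nrow(sets$val), 20 * 6) # originals + 5 copies
  expect_equal(nrow(sets$val), floor(0.1 * 120))
  expect_equal(nrow(sets$test), 6)
  expect_false(any(sets$test$augmented))
  # copies_per_image = 0 leaves the pool untouched
  sets0 <- build_sets(slices, augment_config(copies_per_image = 0),
                      val_frac = 0.1, seed = 1)
  expect_equal(nrow(sets0$train) + nrow(sets0$val), 20)
  expect_false(any(c(sets0$train$augmented, sets0$val$augmented)))
})

test_that("augmentation is uniform across classes and never touches labels", {
  set.seed(3)
  slices <- random_slices(30, grades = c(0, 2, 4), set = "train")
  sets <- build_sets(slices, augment_config(copies_per_image = 3), seed = 7)
  pool <- rbind(sets$train, sets$val)
  orig_counts <- table(factor(slices$grade, levels = 0:4))
  pool_counts <- table(factor(pool$grade, levels = 0:4))
  expect_equal(as.numeric(pool_counts), as.numeric(orig_counts) * 4)
  # per patient-side, labels of augmented copies equal the original's
  key <- paste(pool$patient_id, pool$side)
  for (k in unique(key)) {
    expect_length(unique(pool$grade[key == k]), 1)
  }
})

test_that("no patient crosses the train/test boundary", {
  cohort <- generate_cohort(12, seed = 13)
  sp <- patient_split(cohort, 0.25, seed = 4)
  slices <- isolate_cohort(sp)
  sets <- build_sets(slices, augment_config(copies_per_image = 1), seed = 5)
  expect_length(intersect(unique(c(sets$train$patient_id, sets$val$patient_id)),
                          unique(sets$test$patient_id)), 0)
})
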