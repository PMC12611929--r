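test_that("standardize resizes, converts color and preserves constants", {
  out <- standardize_image(matrix(runif(400 * 600, 0, 255), 400, 600))
  expect_equal(dim(out), c(224, 224))
  img224 <- matrix(runif(224 * 224, 0, 255), 224, 224)
  expect_equal(standardize_image(img224), img224) # identity on target size
  rgb <- array(77, c(50, 60, 3))
  expect_true(all(abs(standardize_image(rgb) - 77) < 1e-9))
  expect_error(standardize_image(matrix(1, 5, 1)), "degenerate")
})

test_that("unsharp masking behaves like its formula", {
  const <- matrix(42, 20, 20)
  expect_equal(sharpen_image(const), const)
  img <- matrix(runif(100, 0, 255), 10, 10)
  expect_equal(sharpen_image(img, amount = 0), img)
  spot <- matrix(0, 5, 5)
  spot[3, 3] <- 100
  expect_gt(sharpen_image(spot, amount = 1, sigma = 1)[3, 3], 100)
  # direct evaluation of the unsharp formula on a 5x5 grid
  manual <- pmin(pmax(spot + 1 * (spot - gaussian_blur(spot, 1)), 0), 255)
  expect_equal(sharpen_image(spot, 1, 1), manual)
  expect_error(sharpen_image(img, amount = -1), "amount")
})

test_that("Otsu matches the exhaustive threshold search", {
  # perfectly bimodal image
  img <- matrix(c(rep(50, 50), rep(200, 50)), 10, 10)
  ot <- otsu_threshold(img)
  expect_true(all(ot$mask[img == 200] == 1))
  expect_true(all(ot$mask[img == 50] == 0))
  # 4x4 toy against the brute-force oracle
  toy <- matrix(c(rep(12, 10), rep(240, 4), 12, 12), 4, 4)
  expect_equal(otsu_threshold(toy)$threshold, otsu_brute_force(toy))
  # random images, exact threshold equality
  set.seed(11)
  for (i in 1:10) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    expect_identical(otsu_threshold(img)$threshold, otsu_brute_force(img))
  }
  expect_error(otsu_threshold(matrix(7, 4, 4)), "degenerate histogram")
})

test_that("morphological opening removes specks and keeps kernel-open shapes", {
  z <- matrix(0L, 9, 9)
  expect_equal(morphological_opening(z, 3), z)
  speck <- z
  speck[5, 5] <- 1L
  expect_equal(morphological_opening(speck, 3), z)
  solid <- matrix(1L, 20, 20)
  expect_equal(morphological_opening(solid, 3), solid)
  expect_error(morphological_opening(matrix(2, 3, 3), 3), "binary")
  # idempotence and agreement with an independent implementation
  set.seed(4)
  for (i in 1:8) {
    m <- matrix(0L, 25, 25)
    m[sample(625, 150)] <- 1L
    op1 <- morphological_opening(m, 3)
    expect_identical(morphological_opening(op1, 3), op1)
    eb <- EBImage::opening(m, EBImage::makeBrush(3, "box"))
    expect_equal(op1, matrix(as.integer(eb), 25, 25))
  }
})

test_that("identical rows are zeroed, idempotently", {
  img <- matrix(seq_len(224 * 10), 10, 224)
  img[c(2, 5, 9), ] <- c(255, 0, 7)
  out <- fix_identical_rows(img)
  expect_true(all(out[c(2, 5, 9), ] == 0))
  expect_equal(out[-c(2, 5, 9), ], img[-c(2, 5, 9), ])
  # brute-force count of constant rows
  const_rows <- apply(img, 1, function(r) length(unique(r)) == 1)
  zero_rows <- apply(out, 1, function(r) all(r == 0))
  expect_equal(zero_rows, const_rows) # exactly the constant rows end up zero
  expect_identical(fix_identical_rows(out), out)
  expect_equal(fix_identical_rows(matrix(1:6, 2, 3)), matrix(1:6, 2, 3))
})

test_that("knee column detection finds, merges and filters runs", {
  mask <- matrix(0L, 6, 16)
  mask[, c(3:6, 11:14)] <- 1L # 0-based columns 2..5 and 10..13
  iv <- detect_knee_columns(mask, min_gap = 3, min_run = 2)
  expect_equal(iv[[1]], c(start = 2L, end = 6L))
  expect_equal(iv[[2]], c(start = 10L, end = 14L))
  # runs separated by fewer than min_gap empty columns merge
  mask2 <- matrix(0L, 6, 30)
  mask2[, c(2:6, 9:12, 21:28)] <- 1L # gap of 2 between first two runs
  iv2 <- detect_knee_columns(mask2, min_gap = 3, min_run = 3)
  expect_equal(iv2[[1]], c(start = 1L, end = 12L))
  expect_equal(iv2[[2]], c(start = 20L, end = 28L))
  expect_error(detect_knee_columns(matrix(0L, 5, 5)),
               class = "kneegrade_separation_error")
  err <- tryCatch(detect_knee_columns(matrix(0L, 5, 5)), condition = identity)
  expect_true(is.list(err$runs))
})

test_that("crops tile the foreground and degenerate intervals fail", {
  img <- matrix(runif(20 * 30, 0, 255), 20, 30)
  mask <- matrix(1L, 20, 30)
  mask[, 15] <- 0L
  iv <- list(c(start = 0L, end = 14L), c(start = 15L, end = 30L))
  crops <- crop_knees(img, iv, mask)
  expect_equal(crops[[1]]$side, "left")
  # crops tile the 29 foreground columns; the separating zero column is
  # excluded from neither interval here, so widths sum to 14 + 15
  expect_equal(ncol(crops[[1]]$pixels) + ncol(crops[[2]]$pixels), 29)
  expect_error(crop_knees(img, list(c(start = 0L, end = 1L), iv[[2]]), mask),
               "degenerate")
})

test_that("zero-padding squares the crop symmetrically and preserves aspect", {
  crop <- matrix(255, 100, 50)
  h <- nrow(crop); w <- ncol(crop)
  out <- pad_and_normalize(crop)
  expect_equal(dim(out), c(224, 224))
  # 25 zero columns on each side before resizing -> content occupies the
  # middle half of the final slice
  content_cols <- range(which(colSums(out) > 0))
  expect_equal(content_cols[1], round(25 / 100 * 224) + 1, tolerance = 2)
  expect_equal(content_cols[2], round(75 / 100 * 224), tolerance = 2)
  expect_equal(max(out), 1)
  # aspect ratio of the content bounding box is preserved after resize
  crop2 <- matrix(0, 80, 40)
  crop2[11:70, 6:35] <- 200 # 60 x 30 content block
  out2 <- pad_and_normalize(crop2)
  rows2 <- range(which(rowSums(out2) > 0.05))
  cols2 <- range(which(colSums(out2) > 0.05))
  ratio <- diff(rows2) / diff(cols2)
  expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("the full isolation pipeline produces valid labeled slices", {
  cohort <- generate_cohort(10, seed = 21)
  slices <- isolate_cohort(cohort)
  expect_equal(nrow(slices), 20)
  for (px in slices$pixels) {
    expect_equal(dim(px), c(224, 224))
    expect_gte(min(px), 0)
    expect_lte(max(px), 1)
    expect_gt(mean(px > 0.05), 0.2) # content-to-padding ratio
  }
  # labels are plumbed through by side
  expect_equal(slices$grade[slices$side == "left"], cohort$grade_left)
  expect_equal(slices$grade[slices$side == "right"], cohort$grade_right)
  # detected source intervals are ordered and disjoint
  for (i in seq_len(nrow(cohort))) {
    l <- slices$source_cols[slices$patient_id == cohort$patient_id[i] &
                              slices$side == "left"][[1]]
    r <- slices$source_cols[slices$patient_id == cohort$patient_id[i] &
                              slices$side == "right"][[1]]
    expect_lte(l[["end"]], r[["start"]])
  }
})

test_that("detected knee intervals match phantom ground truth", {
  cohort <- generate_cohort(15, seed = 33)
  jac <- numeric(0)
  for (i in seq_len(nrow(cohort))) {
    img <- cohort$image[[i]]
    iso <- isolate_knees(img)
    jac <- c(jac,
             column_jaccard(iso$intervals[[1]],
                            scale_truth_cols(cohort$truth_left[[i]], ncol(img))),
             column_jaccard(iso$intervals[[2]],
                            scale_truth_cols(cohort$truth_right[[i]], ncol(img))))
  }
  expect_gte(mean(jac >= 0.8), 0.95)
})
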