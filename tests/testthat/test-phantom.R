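test_that("invalid grades and class mixes are rejected with clear messages", {
  expect_error(generate_phantom(5, 0), "KL grade")
  expect_error(generate_phantom(2, -1), "KL grade")
  expect_error(generate_cohort(3, class_mix = c(0.5, 0.5, 0, 0, -0.1)),
               "class_mix\\[5\\]")
  expect_error(generate_cohort(3, class_mix = c(0.3, 0.3, 0.3, 0.05, 0.04)),
               "sum to 1")
  expect_error(phantom_config(joint_gap_by_grade = c("0" = 12, "1" = 10, "2" = 8,
                                                     "3" = 4, "4" = 1)),
               "image-identical")
  expect_error(phantom_config(background_mean = 250), "background_mean")
})

test_that("the same seed reproduces a bit-identical cohort", {
  a <- generate_cohort(4, seed = 9)
  b <- generate_cohort(4, seed = 9)
  hash <- function(co) vapply(co$image, function(m) rlang::hash(m), "")
  expect_identical(hash(a), hash(b))
  expect_identical(a$grade_left, b$grade_left)
  d <- generate_cohort(4, seed = 10)
  expect_false(identical(hash(a), hash(d)))
})

test_that("truth boxes are in-bounds, column-disjoint and contain the bone pixels", {
  cohort <- generate_cohort(10, seed = 2)
  cfg <- phantom_config()
  for (i in seq_len(nrow(cohort))) {
    img <- cohort$image[[i]]
    tl <- cohort$truth_left[[i]]
    tr <- cohort$truth_right[[i]]
    for (tb in list(tl, tr)) {
      expect_gte(tb[["col_start"]], 0)
      expect_lte(tb[["col_end"]], ncol(img))
      expect_gte(tb[["row_start"]], 0)
      expect_lte(tb[["row_end"]], nrow(img))
    }
    expect_lte(tl[["col_end"]], tr[["col_start"]]) # knees never overlap in columns
    bright <- img >= cfg$bone_intensity - 3 * cfg$noise_sd
    inbox <- matrix(FALSE, nrow(img), ncol(img))
    for (tb in list(tl, tr)) {
      inbox[(tb[["row_start"]] + 1):tb[["row_end"]],
            (tb[["col_start"]] + 1):tb[["col_end"]]] <- TRUE
    }
    expect_gte(sum(bright & inbox) / sum(bright), 0.9)
  }
  expect_true(all(cohort$age >= 40 & cohort$age <= 80))
})

test_that("joint-space gap narrows with grade as configured", {
  cfg <- phantom_config()
  rec4 <- generate_phantom(4, 4, cfg, seed = 0)
  expect_equal(measure_joint_gap(rec4$image[[1]], rec4$truth_left[[1]]), 1)
  expect_equal(measure_joint_gap(rec4$image[[1]], rec4$truth_right[[1]]), 1)
  rec23 <- generate_phantom(2, 3, cfg, seed = 3)
  expect_equal(measure_joint_gap(rec23$image[[1]], rec23$truth_left[[1]]), 8)
  expect_equal(measure_joint_gap(rec23$image[[1]], rec23$truth_right[[1]]), 4)
})

test_that("grade-0 and grade-1 knees come from the same image generator", {
  # swapping the 0/1 labels under the same seed changes nothing but the labels
  a <- generate_phantom(0, 1, seed = 7)
  b <- generate_phantom(1, 0, seed = 7)
  expect_identical(a$image[[1]], b$image[[1]])
  expect_identical(a$truth_left[[1]], b$truth_left[[1]])
  # the pain flag tracks the labeling rule: painful-but-normal film is grade 1
  expect_false(a$pain_left)
  expect_true(a$pain_right)
})

test_that("grade-0 and grade-1 image statistics are indistinguishable", {
  cfg <- phantom_config()
  n <- 100 # 100 knees per class
  stats <- lapply(seq_len(n), function(i) {
    rec <- generate_phantom(0, 1, cfg, seed = 1000 + i)
    img <- rec$image[[1]]
    per_knee <- function(tb) {
      box <- img[(tb[["row_start"]] + 1):tb[["row_end"]],
                 (tb[["col_start"]] + 1):tb[["col_end"]]]
      c(intensity = mean(box[box >= 107]), gap = measure_joint_gap(img, tb))
    }
    list(g0 = per_knee(rec$truth_left[[1]]), g1 = per_knee(rec$truth_right[[1]]))
  })
  g0 <- do.call(rbind, lapply(stats, `[[`, "g0"))
  g1 <- do.call(rbind, lapply(stats, `[[`, "g1"))
  expect_gt(suppressWarnings(ks.test(g0[, "intensity"], g1[, "intensity"]))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(g0[, "gap"], g1[, "gap"]))$p.value, 0.01)
})

test_that("cohort grade frequencies follow the class mix", {
  cohort <- generate_cohort(200, class_mix = rep(0.2, 5), seed = 2)
  grades <- c(cohort$grade_left, cohort$grade_right)
  counts <- tabulate(grades + 1L, 5)
  # 400 knees, each grade Binomial(400, 0.2): stay within 4 SD of expectation
  bound <- 4 * sqrt(400 * 0.2 * 0.8)
  expect_true(all(abs(counts - 80) <= bound))
})

test_that("a degenerate mix produces only that grade", {
  co <- generate_cohort(1, class_mix = c(0, 0, 0, 0, 1), seed = 1)
  expect_equal(co$grade_left, 4L)
  expect_equal(co$grade_right, 4L)
})
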