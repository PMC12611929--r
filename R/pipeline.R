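# End-to-end pipeline orchestration: simulate -> isolate -> split/augment ->
# train -> evaluate, persisting self-describing artifacts.

#' Pipeline run configuration
#'
#' Nested configuration for [run_pipeline()]; every field has a default and
#' a fully defaulted configuration runs end-to-end on synthetic data.
#'
#' @param n_patients Cohort size.
#' @param class_mix Per-grade probabilities (default [kl_class_mix()]).
#' @param test_frac,val_frac Patient-level test fraction and slice-level
#'   validation fraction.
#' @param seed Global seed; per-stage seeds are derived with [derive_seed()].
#' @param phantom,isolation,augment,head,train Stage configurations.
#' @param backbone Backbone name; only `"tiny"` is trainable.
#' @param baselines Also fit the classical-ML baselines.
#' @param write_images Write cohort radiographs as PNG files (requires the
#'   png package).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(n_patients = 60,
                       class_mix = kl_class_mix(),
                       test_frac = 0.2,
                       val_frac = 0.1,
                       seed = 1,
                       phantom = phantom_config(),
                       isolation = isolation_params(),
                       augment = augment_config(copies_per_image = 2),
                       head = head_config(),
                       train = train_config(learning_rate = 1e-3,
                                            max_epochs = 10,
                                            early_stopping_patience = 5),
                       backbone = "tiny",
                       baselines = FALSE,
                       write_images = FALSE) {
  structure(list(n_patients = n_patients, class_mix = class_mix,
                 test_frac = test_frac, val_frac = val_frac, seed = seed,
                 phantom = phantom, isolation = isolation, augment = augment,
                 head = head, train = train, backbone = backbone,
                 baselines = baselines, write_images = write_images),
            class = "run_config")
}

unpack_box <- function(boxes, prefix) {
  out <- do.call(rbind, boxes)
  colnames(out) <- paste(prefix, colnames(out), sep = "_")
  as_tibble(out)
}

#' Run the full pipeline
#'
#' Executes every stage in order -- cohort simulation, knee isolation,
#' patient-level splitting, augmentation, training and evaluation -- and
#' writes `cohort.csv`, `slices.csv`, `split.json`, `history.csv`,
#' `report.json`, `confusion.csv` and a `manifest.json` recording the
#' configuration hash, derived seeds and artifact hashes into `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  seeds <- lapply(setNames(nm = c("cohort", "split", "augment", "init", "train")),
                  function(s) derive_seed(config$seed, s))

  cohort <- generate_cohort(config$n_patients, config$class_mix,
                            config$phantom, seed = seeds$cohort)
  cohort <- patient_split(cohort, config$test_frac, seed = seeds$split)
  cohort_meta <- dplyr::bind_cols(
    cohort[c("patient_id", "age", "sex", "grade_left", "grade_right", "set")],
    unpack_box(cohort$truth_left, "left"),
    unpack_box(cohort$truth_right, "right")
  )
  write.csv(cohort_meta, p("cohort.csv"), row.names = FALSE)
  if (config$write_images) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("write_images = TRUE requires the png package.")
    }
    img_dir <- p("images")
    dir.create(img_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(cohort))) {
      png::writePNG(cohort$image[[i]] / 255,
                    file.path(img_dir, paste0(cohort$patient_id[i], ".png")))
    }
  }

  slices <- isolate_cohort(cohort, config$isolation)
  slice_meta <- dplyr::bind_cols(
    slices[c("patient_id", "side", "grade", "set")],
    unpack_box(slices$source_cols, "col"),
    unpack_box(slices$source_rows, "row")
  )
  write.csv(slice_meta, p("slices.csv"), row.names = FALSE)

  sets <- build_sets(slices, config$augment, config$val_frac, seed = seeds$augment)
  jsonlite::write_json(list(
    train_patients = sort(unique(cohort$patient_id[cohort$set == "train"])),
    test_patients = sort(unique(cohort$patient_id[cohort$set == "test"])),
    n_train = nrow(sets$train), n_val = nrow(sets$val), n_test = nrow(sets$test)
  ), p("split.json"), auto_unbox = TRUE)

  model <- build_model(config$head, config$backbone, seed = seeds$init)
  tc <- config$train
  tc$seed <- tc$seed %||% seeds$train
  fit <- fit_knee_classifier(model, sets, tc)
  write.csv(fit$history, p("history.csv"), row.names = FALSE)

  probs <- predict(fit, sets$test)
  report <- evaluate_predictions(as.integer(sets$test$grade), probs)
  write_metrics_report(report, p("report.json"))
  counts <- confusion_counts(as.integer(sets$test$grade), probs)
  write.csv(counts, p("confusion.csv"), row.names = FALSE)

  if (isTRUE(config$baselines)) {
    write.csv(fit_baselines(sets, seed = seeds$train), p("baselines.csv"),
              row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("kneegrade")),
    seed = config$seed,
    stage_seeds = seeds,
    config_hash = rlang::hash(config),
    cohort_hash = rlang::hash(lapply(cohort$image, image_hash)),
    split_hash = rlang::hash(cohort[c("patient_id", "set")]),
    n_patients = nrow(cohort),
    n_test_patients = sum(cohort$set == "test"),
    n_slices = nrow(slices),
    best_epoch = fit$best_epoch,
    artifacts = c("cohort.csv", "slices.csv", "split.json", "history.csv",
                  "report.json", "confusion.csv")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
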