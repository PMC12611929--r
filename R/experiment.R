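# Desk-scale qualitative-finding recovery: on phantoms, severity grades 2-4
# are separable by construction (distinct joint gaps and osteophyte counts)
# while grades 0 and 1 are image-identical; a trained classifier should
# therefore recover grades 2-4 with high recall while 0-vs-1 discrimination
# stays at chance.

#' Run the desk-scale grade-recovery experiment
#'
#' Generates a phantom training cohort, isolates and augments it with a
#' patient-level 80/20 split, trains the compact executable classifier, and
#' evaluates on two independently generated phantom sets: a severity set
#' (grades 2-4 only) for macro recall, and a balanced grade-0/1 set for the
#' confusability analysis.
#'
#' @param seed Integer seed; all stages derive their seeds from it.
#' @param n_train_patients Patients in the training cohort (uniform grade
#'   mix).
#' @param n_recall_patients Patients in the severity evaluation cohort
#'   (grades 2-4, uniform).
#' @param n_confusability_patients Patients in the grade-0/1 cohort; each
#'   radiograph carries one grade-0 and one grade-1 knee.
#' @param copies_per_image Augmented copies per training slice.
#' @param max_epochs,learning_rate,batch_size Training budget, Adam step
#'   size and minibatch size for the compact profile.
#' @param verbose Print stage progress.
#' @return A list with `fit`, `report_test` (held-out patient test metrics),
#'   `recall_234` (macro recall over grades 2-4 on the severity set),
#'   `per_class_recall`, `confusability` (see [grade01_confusability()]),
#'   and `sizes`.
#' @export
grade_recovery_experiment <- function(seed = 1,
                                      n_train_patients = 100,
                                      n_recall_patients = 36,
                                      n_confusability_patients = 110,
                                      copies_per_image = 2,
                                      max_epochs = 40,
                                      learning_rate = 1.5e-3,
                                      batch_size = 8,
                                      verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  cfg <- phantom_config()
  iso <- isolation_params()

  say("Generating training cohort (%d patients)...", n_train_patients)
  cohort <- generate_cohort(n_train_patients, class_mix = rep(0.2, 5),
                            cfg = cfg, seed = derive_seed(seed, "cohort"))
  cohort <- patient_split(cohort, 0.2, seed = derive_seed(seed, "split"))
  slices <- isolate_cohort(cohort, iso)
  sets <- build_sets(slices, augment_config(copies_per_image = copies_per_image),
                     val_frac = 0.1, seed = derive_seed(seed, "augment"))

  say("Training compact classifier (%d train slices)...", nrow(sets$train))
  model <- build_model(head_config(), backbone = "tiny",
                       seed = derive_seed(seed, "init"))
  fit <- fit_knee_classifier(model, sets, train_config(
    learning_rate = learning_rate, batch_size = batch_size,
    max_epochs = max_epochs, lr_patience = 6, early_stopping_patience = 15,
    seed = derive_seed(seed, "train")))

  say("Evaluating on held-out patients...")
  report_test <- evaluate_model(fit, sets$test)

  say("Severity recovery on grades 2-4 (%d patients)...", n_recall_patients)
  sev <- generate_cohort(n_recall_patients, class_mix = c(0, 0, 1, 1, 1) / 3,
                         cfg = cfg, seed = derive_seed(seed, "severity"))
  sev_slices <- isolate_cohort(sev, iso)
  sev_probs <- predict(fit, sev_slices)
  counts <- confusion_counts(as.integer(sev_slices$grade), sev_probs)
  per_class <- counts[counts$support > 0, ]
  per_class$recall <- per_class$tp / (per_class$tp + per_class$fn)
  recall_234 <- mean(per_class$recall[per_class$class %in% 2:4])

  say("Grade-0/1 confusability (%d patients)...", n_confusability_patients)
  conf <- bind_rows(lapply(seq_len(n_confusability_patients), function(i) {
    g <- if (i %% 2 == 0) c(0, 1) else c(1, 0) # alternate sides
    generate_phantom(g[1], g[2], cfg = cfg,
                     seed = derive_seed(seed, paste0("confus", i)),
                     patient_id = sprintf("C%04d", i))
  }))
  conf_slices <- isolate_cohort(conf, iso)
  conf_probs <- predict(fit, conf_slices)
  confusability <- grade01_confusability(as.integer(conf_slices$grade), conf_probs)

  list(fit = fit,
       report_test = report_test,
       recall_234 = recall_234,
       per_class_recall = per_class[c("class", "support", "recall")],
       confusability = confusability,
       sizes = list(n_train_slices = nrow(sets$train),
                    n_val_slices = nrow(sets$val),
                    n_test_slices = nrow(sets$test),
                    n_severity_knees = nrow(sev_slices),
                    n_confusability_knees = nrow(conf_slices)))
}
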