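# Training loop for the executable classifier profile, classical-ML
# baselines, and the grade-0/1 confusability analysis.

#' Training configuration
#'
#' Adam with a reduce-on-plateau learning-rate schedule and early stopping,
#' both monitored on validation loss. The best-validation-loss weights are
#' restored at the end.
#'
#' @param learning_rate Initial Adam step size.
#' @param lr_factor,lr_patience Multiply the learning rate by `lr_factor`
#'   after `lr_patience` epochs without validation-loss improvement.
#' @param early_stopping_patience Stop after this many epochs without
#'   validation-loss improvement.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch budget.
#' @param seed Seed controlling shuffling, dropout and initialization.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-4, lr_factor = 0.5, lr_patience = 3,
                         early_stopping_patience = 10, batch_size = 16,
                         max_epochs = 100, seed = NULL) {
  stopifnot(learning_rate >= 0, lr_patience >= 1, early_stopping_patience >= 1,
            batch_size >= 1, max_epochs >= 1, lr_factor > 0, lr_factor <= 1)
  structure(list(learning_rate = learning_rate, lr_factor = lr_factor,
                 lr_patience = lr_patience,
                 early_stopping_patience = early_stopping_patience,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = seed),
            class = "train_config")
}

epoch_metrics <- function(y_true, y_prob) {
  counts <- confusion_counts(y_true, y_prob)
  auc <- tryCatch(suppressWarnings(ovr_auc(y_true, y_prob)),
                  error = function(e) NA_real_)
  list(loss = categorical_cross_entropy(y_true, y_prob),
       accuracy = categorical_accuracy(y_true, y_prob),
       auc = auc,
       precision = suppressWarnings(macro_precision(counts)),
       recall = macro_recall(counts))
}

#' Train the KL-grade classifier
#'
#' Minimizes categorical cross-entropy (plus the head's L2 penalty) with
#' Adam on the training slices, tracking loss, accuracy, AUC, precision and
#' recall per epoch on both training and validation sets. Training metrics
#' are computed from the probabilities observed during the training passes.
#'
#' @param model An executable `"kg_model"` (built with `backbone = "tiny"`).
#' @param split A `"cohort_split"` from [build_sets()].
#' @param config A [train_config()].
#' @return A list of class `"kg_fit"`: the trained `network`, the per-epoch
#'   `history` tibble, `best_epoch`, `classes`, and the configs.
#' @export
fit_knee_classifier <- function(model, split, config = train_config()) {
  stopifnot(inherits(model, "kg_model"), inherits(split, "cohort_split"))
  if (is.null(model$network)) {
    abort("Model is accounting-only; build with backbone = \"tiny\" to train.")
  }
  if (nrow(split$train) == 0 || nrow(split$val) == 0) {
    abort("Training and validation sets must be non-empty.")
  }
  if (!is.null(config$seed)) withr::local_seed(config$seed)

  net <- net_duplicate_params(model$network) # optimizer updates are in place
  n_classes <- model$head$n_classes
  xs <- lapply(split$train$pixels, function(px) { dim(px) <- c(dim(px), 1); px })
  ys <- as.integer(split$train$grade)
  val_y <- as.integer(split$val$grade)

  state <- adam_init(net)
  lr <- config$learning_rate
  t_step <- 0
  history <- list()
  best <- list(val_loss = Inf, epoch = 0L, params = net_get_params(net))
  lr_wait <- 0L; stop_wait <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(xs))
    train_probs <- matrix(NA_real_, length(xs), n_classes)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    for (bi in batches) {
      grads_acc <- NULL
      for (i in bi) {
        fw <- net_forward(net, xs[[i]], training = TRUE)
        sm <- softmax_cce(fw$out, ys[i])
        train_probs[i, ] <- sm$probs
        epoch_loss <- epoch_loss + sm$loss
        g <- net_backward(net, fw$caches, sm$dlogits / length(bi))
        if (is.null(grads_acc)) {
          grads_acc <- g # sole owner: freshly allocated by net_backward
        } else {
          for (k in seq_along(g)) {
            if (!is.null(g[[k]])) {
              axpy_inplace_cpp(grads_acc[[k]]$W, g[[k]]$W)
              axpy_inplace_cpp(grads_acc[[k]]$b, g[[k]]$b)
            }
          }
        }
      }
      t_step <- t_step + 1
      upd <- adam_step(net, grads_acc, state, lr, t_step)
      net <- upd$net; state <- upd$state
    }
    train_loss <- epoch_loss / length(xs) + net_l2_penalty(net)
    if (!is.finite(train_loss)) {
      abort(sprintf("Training diverged: non-finite loss at epoch %d.", epoch))
    }
    tm <- epoch_metrics(ys, train_probs)
    val_probs <- net_predict_probs(net, split$val$pixels)
    vm <- epoch_metrics(val_y, val_probs)
    history[[epoch]] <- tibble(
      epoch = epoch, lr = lr,
      loss = train_loss, accuracy = tm$accuracy, auc = tm$auc,
      precision = tm$precision, recall = tm$recall,
      val_loss = vm$loss, val_accuracy = vm$accuracy, val_auc = vm$auc,
      val_precision = vm$precision, val_recall = vm$recall
    )
    if (vm$loss < best$val_loss - 1e-8) {
      best <- list(val_loss = vm$loss, epoch = epoch, params = net_get_params(net))
      lr_wait <- 0L; stop_wait <- 0L
    } else {
      lr_wait <- lr_wait + 1L; stop_wait <- stop_wait + 1L
      if (lr_wait >= config$lr_patience) {
        lr <- lr * config$lr_factor
        lr_wait <- 0L
      }
      if (stop_wait >= config$early_stopping_patience) break
    }
  }
  net <- net_set_params(net, best$params)
  structure(list(network = net, history = bind_rows(history),
                 best_epoch = best$epoch, classes = 0:(n_classes - 1),
                 head = model$head, backbone = model$backbone$name,
                 config = config),
            class = "kg_fit")
}

#' Predict class probabilities or classes
#'
#' @param object A `"kg_fit"` from [fit_knee_classifier()].
#' @param newdata A slice tibble with a `pixels` list-column, or a list of
#'   `224 x 224` matrices.
#' @param type `"prob"` for an `n x K` probability matrix, `"class"` for
#'   argmax labels.
#' @param ... Unused.
#' @export
predict.kg_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  pixels <- if (is.data.frame(newdata)) newdata$pixels else newdata
  probs <- net_predict_probs(object$network, pixels)
  if (type == "prob") probs else argmax0(probs)
}

#' Evaluate a fitted classifier on a slice set
#'
#' @param fit A `"kg_fit"`.
#' @param slices Slice tibble with `pixels` and `grade` columns.
#' @return A `"kg_metrics_report"` tibble (see [evaluate_predictions()]).
#' @export
evaluate_model <- function(fit, slices) {
  probs <- predict(fit, slices)
  evaluate_predictions(as.integer(slices$grade), probs)
}

#' @export
tidy.kg_fit <- function(x, ...) {
  long <- tidyr::pivot_longer(x$history, -c("epoch", "lr"),
                              names_to = "metric", values_to = "value")
  long$phase <- ifelse(grepl("^val_", long$metric), "validation", "training")
  long$metric <- sub("^val_", "", long$metric)
  long[c("epoch", "phase", "metric", "value", "lr")]
}

#' @export
glance.kg_fit <- function(x, ...) {
  best <- x$history[x$best_epoch, ]
  tibble(epochs_run = nrow(x$history), best_epoch = x$best_epoch,
         best_val_loss = best$val_loss, best_val_accuracy = best$val_accuracy)
}

#' @export
autoplot.kg_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   color = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL, color = NULL,
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' Baseline configuration
#'
#' Classical-ML comparison settings: a decision tree split on information
#' gain (entropy), an RBF support vector machine with regularization
#' strength 0.5 and one-vs-one multiclass decisions, and a 500-tree random
#' forest. Inputs are slices flattened to vectors and standardized feature-
#' wise to zero mean / unit variance on the training set.
#'
#' @param svm_cost SVM regularization strength.
#' @param svm_kernel `"radial"` (default) or `"linear"`.
#' @param rf_trees Number of random-forest trees.
#' @param use_augmented Fit baselines on the augmented pool instead of the
#'   original training slices (default `FALSE`; augmentation is a deep-model
#'   training device).
#' @return A list of class `"baseline_config"`.
#' @export
baseline_config <- function(svm_cost = 0.5, svm_kernel = c("radial", "linear"),
                            rf_trees = 500, use_augmented = FALSE) {
  stopifnot(rf_trees >= 1, svm_cost > 0)
  structure(list(svm_cost = svm_cost, svm_kernel = match.arg(svm_kernel),
                 rf_trees = as.integer(rf_trees),
                 use_augmented = isTRUE(use_augmented)),
            class = "baseline_config")
}

flatten_slices <- function(slices) {
  t(vapply(slices$pixels, as.numeric, numeric(length(slices$pixels[[1]]))))
}

#' Entropy-criterion decision tree
#'
#' A CART-style classification tree with greedy binary splits chosen by
#' information gain (entropy criterion), operating directly on a feature
#' matrix. Formula-based tree fitters build terms machinery that is
#' quadratic in the number of predictors, which is infeasible for slices
#' flattened to ~50k features; this implementation works at that width.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Class labels (factor or integers).
#' @param max_depth Maximum tree depth.
#' @param min_split Minimum node size eligible for splitting.
#' @return An object of class `"kg_entropy_tree"` with a `predict()` method.
#' @export
entropy_tree <- function(x, y, max_depth = 10, min_split = 5) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  yf <- as.factor(y)
  fit <- entropy_tree_fit_cpp(x, as.integer(yf) - 1L, nlevels(yf),
                              as.integer(max_depth), as.integer(min_split))
  structure(list(tree = fit, levels = levels(yf)), class = "kg_entropy_tree")
}

#' @export
predict.kg_entropy_tree <- function(object, newdata, ...) {
  idx <- entropy_tree_predict_cpp(object$tree, as.matrix(newdata))
  factor(object$levels[idx + 1L], levels = object$levels)
}

#' Fit the classical-ML baselines
#'
#' Flattens each slice to a feature vector, standardizes features with
#' training-set statistics, and fits a decision tree ([entropy_tree()],
#' entropy criterion), an SVM (one-vs-one) and a random forest, reporting
#' test accuracy for each. Note the random forest uses the Gini criterion:
#' R's randomForest does not expose an entropy split rule.
#'
#' @param split A `"cohort_split"` from [build_sets()].
#' @param config A [baseline_config()].
#' @param seed Seed for the stochastic learners.
#' @return A tibble with columns `algorithm`, `accuracy`, `details`.
#' @export
fit_baselines <- function(split, config = baseline_config(), seed = NULL) {
  stopifnot(inherits(split, "cohort_split"))
  if (!is.null(seed)) withr::local_seed(seed)
  train <- if (config$use_augmented) split$train else {
    dplyr::filter(split$train, !.data$augmented)
  }
  if (length(unique(train$grade)) < 2) {
    abort("Baselines need at least 2 classes in the training set.")
  }
  x_train <- flatten_slices(train)
  x_test <- flatten_slices(split$test)
  mu <- colMeans(x_train)
  sg <- apply(x_train, 2, sd)
  sg[sg == 0] <- 1
  x_train <- scale(x_train, center = mu, scale = sg)
  x_test <- scale(x_test, center = mu, scale = sg)
  y_train <- factor(train$grade) # only classes present in training
  y_test <- factor(split$test$grade)

  acc <- function(pred) mean(as.character(pred) == as.character(y_test))

  tree_fit <- entropy_tree(x_train, y_train)
  tree_acc <- acc(predict(tree_fit, x_test))

  svm_fit <- e1071::svm(x_train, y_train, cost = config$svm_cost,
                        kernel = config$svm_kernel, scale = FALSE)
  svm_acc <- acc(predict(svm_fit, x_test))

  rf_fit <- randomForest::randomForest(x_train, y_train, ntree = config$rf_trees)
  rf_acc <- acc(predict(rf_fit, x_test))

  tibble(
    algorithm = c("decision_tree", "svm", "random_forest"),
    accuracy = c(tree_acc, svm_acc, rf_acc),
    details = c("criterion = entropy",
                sprintf("cost = %g, kernel = %s, decision = ovo",
                        config$svm_cost, config$svm_kernel),
                sprintf("criterion = gini, n_trees = %d", config$rf_trees))
  )
}

#' Grade-0 vs grade-1 confusability analysis
#'
#' Restricted to samples whose true grade is 0 or 1, reports how often the
#' prediction stays within \{0, 1\}, the 0-vs-1 accuracy, and the 0-vs-1
#' discrimination AUC (scoring each sample by its renormalized grade-1
#' probability). On phantoms, where grade-0 and grade-1 images are drawn
#' from the same generator, the discrimination AUC is expected at chance.
#'
#' @param y_true Integer grades.
#' @param y_prob `n x 5` probability matrix.
#' @return A one-row tibble: `n0`, `n1`, `p_pred_within_01`, `acc_01`,
#'   `auc_01`.
#' @export
grade01_confusability <- function(y_true, y_prob) {
  check_prob_matrix(y_true, y_prob)
  sel <- y_true %in% c(0, 1)
  if (!any(y_true[sel] == 0) || !any(y_true[sel] == 1)) {
    abort("Both grade 0 and grade 1 must be present in the truth.")
  }
  yt <- y_true[sel]
  yp <- y_prob[sel, , drop = FALSE]
  score1 <- yp[, 2] / (yp[, 1] + yp[, 2])
  pred01 <- as.integer(yp[, 2] > yp[, 1])
  tibble(
    n0 = sum(yt == 0), n1 = sum(yt == 1),
    p_pred_within_01 = mean(argmax0(yp) %in% c(0, 1)),
    acc_01 = mean(pred01 == yt),
    auc_01 = rank_auc(score1, yt == 1)
  )
}

#' Merge grades 0 and 1 and recompute accuracy
#'
#' Accuracy after collapsing the two radiographically identical grades into
#' one class (predictions and truth in \{0,1\} both map to the merged
#' class). Merging confusable classes can never lower accuracy.
#'
#' @inheritParams grade01_confusability
#' @return Merged 4-class accuracy.
#' @export
merged01_accuracy <- function(y_true, y_prob) {
  check_prob_matrix(y_true, y_prob)
  pred <- argmax0(y_prob)
  merge <- function(g) ifelse(g <= 1, 0L, g)
  mean(merge(pred) == merge(y_true))
}
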