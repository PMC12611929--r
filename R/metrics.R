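# Evaluation metrics: categorical accuracy, one-vs-rest AUC, macro recall and
# precision from one-vs-rest confusion counts, and categorical cross-entropy.
#
# Conventions: predictions are the argmax of the probability rows with ties
# broken to the lowest class index; AUC uses the rank (Mann-Whitney)
# statistic with half-credit for ties, equivalent to trapezoidal integration
# of the empirical ROC curve; averaging is macro over classes present in the
# truth, with micro variants available.

check_prob_matrix <- function(y_true, y_prob, tol = 1e-6) {
  if (!is.matrix(y_prob)) abort("y_prob must be a matrix (samples x classes).")
  if (length(y_true) != nrow(y_prob)) {
    abort(sprintf("length mismatch: %d labels vs %d probability rows.",
                  length(y_true), nrow(y_prob)))
  }
  rs <- rowSums(y_prob)
  if (any(abs(rs - 1) > tol)) {
    abort(sprintf("probability rows must sum to 1 (worst deviation %.3g).",
                  max(abs(rs - 1))))
  }
  invisible(TRUE)
}

#' One-vs-rest confusion counts
#'
#' Binarizes argmax predictions one class against the rest and tabulates
#' TP / FP / TN / FN per class.
#'
#' @param y_true Integer labels in `0..K-1`.
#' @param y_prob `n x K` matrix of class probabilities.
#' @return A tibble of class `"kg_confusion"` with columns `class`, `tp`,
#'   `fp`, `tn`, `fn`, `support`.
#' @export
confusion_counts <- function(y_true, y_prob) {
  check_prob_matrix(y_true, y_prob)
  k <- ncol(y_prob)
  pred <- argmax0(y_prob)
  out <- lapply(0:(k - 1), function(cl) {
    tp <- sum(y_true == cl & pred == cl)
    fp <- sum(y_true != cl & pred == cl)
    fn <- sum(y_true == cl & pred != cl)
    tn <- sum(y_true != cl & pred != cl)
    tibble(class = cl, tp = tp, fp = fp, tn = tn, fn = fn,
           support = sum(y_true == cl))
  })
  structure(bind_rows(out), class = c("kg_confusion", class(tibble())))
}

#' Categorical accuracy
#'
#' Fraction of samples whose argmax prediction equals the true label.
#'
#' @inheritParams confusion_counts
#' @return Accuracy in `[0, 1]`.
#' @export
categorical_accuracy <- function(y_true, y_prob) {
  check_prob_matrix(y_true, y_prob)
  mean(argmax0(y_prob) == y_true)
}

# binary rank-statistic AUC with half-credit for ties
rank_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest multiclass ROC AUC
#'
#' Per class, the area under the empirical ROC curve of that class's
#' probability against all other classes, computed by the Mann-Whitney rank
#' statistic (half-credit for score ties); averaged over evaluable classes
#' (macro) or computed on the pooled one-vs-rest pairs (micro). Classes
#' absent from the truth are skipped with a warning.
#'
#' @inheritParams confusion_counts
#' @param average `"macro"` (default) or `"micro"`.
#' @return AUC in `[0, 1]`.
#' @export
ovr_auc <- function(y_true, y_prob, average = c("macro", "micro")) {
  average <- match.arg(average)
  check_prob_matrix(y_true, y_prob)
  k <- ncol(y_prob)
  present <- sort(unique(y_true))
  if (length(present) < 2) abort("AUC undefined: truth contains a single class.")
  absent <- setdiff(0:(k - 1), present)
  if (length(absent)) {
    warn(sprintf("Classes absent from truth skipped in AUC: %s.",
                 paste(absent, collapse = ", ")))
  }
  if (average == "macro") {
    aucs <- vapply(present, function(cl) {
      rank_auc(y_prob[, cl + 1], y_true == cl)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  } else {
    scores <- as.numeric(y_prob[, present + 1])
    labels <- as.logical(vapply(present, function(cl) y_true == cl,
                                logical(length(y_true))))
    rank_auc(scores, labels)
  }
}

#' Macro-averaged recall and precision
#'
#' Per-class `TP / (TP + FN)` (recall) and `TP / (TP + FP)` (precision),
#' macro-averaged. Recall averages over classes present in the truth;
#' precision additionally scores 0 (with a warning) for a class that was
#' never predicted.
#'
#' @param counts A `"kg_confusion"` tibble from [confusion_counts()].
#' @return A scalar in `[0, 1]`.
#' @export
macro_recall <- function(counts) {
  stopifnot(inherits(counts, "kg_confusion"))
  present <- counts[counts$support > 0, ]
  mean(present$tp / (present$tp + present$fn))
}

#' @rdname macro_recall
#' @export
macro_precision <- function(counts) {
  stopifnot(inherits(counts, "kg_confusion"))
  present <- counts[counts$support > 0, ]
  denom <- present$tp + present$fp
  if (any(denom == 0)) {
    warn(sprintf("Precision denominators are zero for class(es) %s; scored 0.",
                 paste(present$class[denom == 0], collapse = ", ")))
  }
  mean(ifelse(denom == 0, 0, present$tp / pmax(denom, 1)))
}

#' Per-class specificity
#'
#' `TN / (TN + FP)` per class. Provided alongside precision because the two
#' are sometimes conflated; they are different quantities.
#'
#' @inheritParams macro_recall
#' @return A tibble with columns `class` and `specificity`.
#' @export
class_specificity <- function(counts) {
  stopifnot(inherits(counts, "kg_confusion"))
  tibble(class = counts$class,
         specificity = counts$tn / (counts$tn + counts$fp))
}

#' Categorical cross-entropy
#'
#' Mean over samples of `-sum_i y_i log(p_i)` (natural log), with predicted
#' probabilities clipped to `[1e-7, 1]` before the log.
#'
#' @param y_true Integer labels in `0..K-1`, or an `n x K` one-hot matrix.
#' @param y_prob `n x K` matrix of class probabilities; rows must sum to 1
#'   within `1e-5`.
#' @param eps Clipping floor for predicted probabilities.
#' @return Mean loss (>= 0).
#' @export
categorical_cross_entropy <- function(y_true, y_prob, eps = 1e-7) {
  if (is.matrix(y_true)) {
    if (!all(dim(y_true) == dim(y_prob))) abort("one-hot truth shape mismatch.")
    y_true <- argmax0(y_true)
  }
  check_prob_matrix(y_true, y_prob, tol = 1e-5)
  p <- clip(y_prob[cbind(seq_along(y_true), y_true + 1L)], eps, 1)
  mean(-log(p))
}

#' Evaluate predictions into a metrics report
#'
#' Computes the full evaluation row -- categorical cross-entropy loss,
#' categorical accuracy, macro one-vs-rest AUC, macro precision, macro
#' recall -- plus micro AUC as a companion column.
#'
#' @inheritParams confusion_counts
#' @return A one-row tibble of class `"kg_metrics_report"` with columns
#'   `loss`, `accuracy`, `auc`, `precision`, `recall`, `auc_micro`.
#' @export
#' @examples
#' y <- c(0, 1, 2, 1)
#' p <- matrix(0.05, 4, 3); p[cbind(1:4, y + 1)] <- 0.9
#' evaluate_predictions(y, p / rowSums(p))
evaluate_predictions <- function(y_true, y_prob) {
  counts <- confusion_counts(y_true, y_prob)
  out <- tibble(
    loss = categorical_cross_entropy(y_true, y_prob),
    accuracy = categorical_accuracy(y_true, y_prob),
    auc = ovr_auc(y_true, y_prob, "macro"),
    precision = macro_precision(counts),
    recall = macro_recall(counts),
    auc_micro = ovr_auc(y_true, y_prob, "micro")
  )
  structure(out, class = c("kg_metrics_report", class(tibble())))
}

#' Serialize / deserialize a metrics report
#'
#' Lossless JSON round-trip for a `"kg_metrics_report"`.
#'
#' @param report A metrics report tibble.
#' @param path File path.
#' @return `read_metrics_report()` returns the report tibble.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(as_tibble(x), class = c("kg_metrics_report", class(tibble())))
}
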