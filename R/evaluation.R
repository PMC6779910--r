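# Cross-validated accuracy assessment and confusion-matrix drill-down:
# the "Test and Score -> Confusion Matrix" chain as library operations.

# Deterministic stratified fold assignment. Within each class the shuffled
# members are dealt round-robin; a running offset carries the deal across
# classes so overall fold sizes stay balanced. Per-class fold counts differ
# by at most one from exact proportionality.
stratified_folds <- function(labels, k, seed) {
  classes <- sort_bytewise(unique(labels))
  counts <- table(factor(labels, levels = classes))
  too_small <- names(counts)[counts < k]
  if (length(too_small)) {
    abort_input(sprintf(
      "stratified %d-fold CV impossible: class(es) %s have fewer than %d examples; reduce `k`",
      k, paste(sprintf("'%s' (%d)", too_small, counts[too_small]), collapse = ", "), k))
  }
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L
  for (cls in classes) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- (seq_along(idx) - 1L + offset) %% k
    offset <- (offset + length(idx)) %% k
  }
  fold
}

#' Cross-validated evaluation of a logistic-regression classifier
#'
#' Stratified k-fold cross-validation: samples are split into `k` folds with
#' near-equal class proportions (shuffled with `seed`), a fresh model is
#' trained on each set of `k - 1` folds and predicts the held-out fold, and
#' the out-of-fold predictions and class probabilities are assembled in
#' table order — every sample is predicted exactly once by a model that
#' never saw it.
#'
#' @param E A labeled `embedding_matrix`.
#' @param learner List of [train_logreg()] hyperparameters
#'   (default `list(C = 1, max_iter = 1000)`).
#' @param k Number of folds (default 10).
#' @param seed Shuffle seed (default 0).
#' @return A `cv_result`: `true_labels`, `predicted_labels`,
#'   `probabilities` (`n x #classes`), `fold_of` (0-based), `classes`, and
#'   the source `table`.
#' @export
cross_validate <- function(E, learner = list(), k = 10L, seed = 0L) {
  if (!inherits(E, "embedding_matrix")) abort_input("`E` must be an embedding_matrix")
  stopifnot_count(k, "k", min = 2L)
  learner <- modifyList(list(C = 1, max_iter = 1000L), learner)
  labels <- E$table$label
  if (anyNA(labels)) {
    abort_input(sprintf(
      "cross-validation needs a fully labeled table; %d records (e.g. '%s') have no label",
      sum(is.na(labels)), E$table$path[which(is.na(labels))[1L]]))
  }
  classes <- sort_bytewise(unique(labels))
  if (length(classes) < 2L) abort_input("cross-validation needs at least 2 classes")
  fold <- stratified_folds(labels, k, seed)
  n <- nrow(E$values)
  probs <- matrix(NA_real_, n, length(classes), dimnames = list(NULL, classes))
  pred <- character(n)
  for (f in 0:(k - 1L)) {
    test <- which(fold == f)
    train <- which(fold != f)
    model <- train_logreg(subset_embedding(E, train), C = learner$C,
                          max_iter = learner$max_iter, seed = seed)
    P <- predict_proba(model, E$values[test, , drop = FALSE])
    probs[test, model$classes] <- P
    pred[test] <- predict_class(model, E$values[test, , drop = FALSE])
  }
  structure(list(true_labels = labels, predicted_labels = pred,
                 probabilities = probs, fold_of = fold, classes = classes,
                 table = E$table,
                 learner = learner, k = as.integer(k), seed = as.integer(seed)),
            class = "cv_result")
}

#' @method print cv_result
#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d samples, %d classes, %d-fold stratified CV (seed %d)\n",
              length(x$true_labels), length(x$classes), x$k, x$seed))
  cat(sprintf("out-of-fold accuracy: %.3f\n",
              mean(x$true_labels == x$predicted_labels)))
  invisible(x)
}

#' Confusion matrix of a cross-validation result
#'
#' `counts[i, j]` is the number of samples of true class `i` predicted as
#' class `j`; rows and columns follow the class order of the evaluation.
#'
#' @param ev A `cv_result` (or anything with `true_labels`,
#'   `predicted_labels`, `classes`).
#' @return An integer `confusion_matrix` with class dimnames.
#' @export
confusion_matrix <- function(ev) {
  classes <- ev$classes
  counts <- table(factor(ev$true_labels, levels = classes),
                  factor(ev$predicted_labels, levels = classes))
  m <- matrix(as.integer(counts), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Build a confusion matrix from printed counts
#'
#' For worked examples quoted from the literature: wraps a plain count
#' matrix (rows = true class, columns = predicted class) as a
#' `confusion_matrix` so that [compute_metrics()] applies.
#'
#' @param counts Square nonnegative integer matrix.
#' @param classes Class labels, one per row.
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts, classes) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) != length(classes)) {
    abort_input("`counts` must be square with one row per class")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_input("`counts` must be nonnegative integers")
  }
  m <- matrix(as.integer(counts), nrow(counts), ncol(counts),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' @method print confusion_matrix
#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = true, columns = predicted\n")
  print(unclass(x))
  invisible(x)
}

# Mann-Whitney AUC via pROC; NA when a class has no positives or negatives.
binary_auc <- function(response, predictor) {
  if (length(unique(response)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response, predictor,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

#' Classification metrics from an evaluation result or confusion matrix
#'
#' Classification accuracy (CA = trace/total), one-vs-rest precision,
#' recall and F1 per class (F1 = 0 when precision + recall = 0), macro
#' (unweighted mean) and weighted (support-weighted mean) F1, and — when
#' out-of-fold class probabilities are available — macro one-vs-rest AUC.
#' The headline `F1` field is the positive-class F1 for binary problems
#' (positive = the later class in sorted order) and the weighted F1 for
#' multiclass; all variants are always reported alongside.
#'
#' @param ev A `cv_result`, or a `confusion_matrix` (then AUC is `NA`).
#' @return A `classification_metrics` list: `CA`, `per_class` (data frame
#'   with precision/recall/F1/support), `F1_per_class`, `F1_macro`,
#'   `F1_weighted`, `F1`, `AUC_macro_ovr`, `n`.
#' @export
compute_metrics <- function(ev) {
  if (inherits(ev, "confusion_matrix")) {
    cm <- ev
    probs <- NULL
    true <- NULL
  } else {
    cm <- confusion_matrix(ev)
    probs <- ev$probabilities
    true <- ev$true_labels
  }
  classes <- rownames(cm)
  n <- sum(cm)
  CA <- sum(diag(cm)) / n
  support <- rowSums(cm)
  precision <- recall <- f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    tp <- cm[i, i]
    precision[i] <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    recall[i] <- if (support[i] > 0) tp / support[i] else 0
    f1[i] <- if (precision[i] + recall[i] > 0) {
      2 * precision[i] * recall[i] / (precision[i] + recall[i])
    } else 0
  }
  auc <- if (!is.null(probs)) {
    per_class_auc <- vapply(classes, function(cls) {
      binary_auc(true == cls, probs[, cls])
    }, numeric(1))
    mean(per_class_auc, na.rm = TRUE)
  } else {
    NA_real_
  }
  headline <- if (length(classes) == 2L) f1[2L] else sum(f1 * support) / n
  structure(list(
    CA = CA,
    per_class = data.frame(class = classes, precision = precision,
                           recall = recall, F1 = f1, support = as.integer(support),
                           stringsAsFactors = FALSE),
    F1_per_class = setNames(f1, classes),
    F1_macro = mean(f1),
    F1_weighted = sum(f1 * support) / n,
    F1 = headline,
    AUC_macro_ovr = auc,
    n = as.integer(n)
  ), class = "classification_metrics")
}

#' @method print classification_metrics
#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("CA = %.3f  F1 = %.3f (macro %.3f, weighted %.3f)  AUC = %s  [n = %d]\n",
              x$CA, x$F1, x$F1_macro, x$F1_weighted,
              if (is.na(x$AUC_macro_ovr)) "NA" else sprintf("%.3f", x$AUC_macro_ovr),
              x$n))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Select the images behind one confusion-matrix cell
#'
#' The programmatic analogue of clicking a cell in an interactive confusion
#' matrix: returns the records whose true class is `true_class` and whose
#' out-of-fold prediction is `predicted_class`, in table order, ready to be
#' passed to an image viewer or highlighted in a projection
#' ([mark_subset()]).
#'
#' @param ev A `cv_result`.
#' @param true_class,predicted_class Class names.
#' @return An `image_table` subset (possibly empty).
#' @export
select_cell <- function(ev, true_class, predicted_class) {
  for (cls in c(true_class, predicted_class)) {
    if (!cls %in% ev$classes) {
      abort_input(sprintf("unknown class '%s' (classes: %s)", cls,
                          paste(ev$classes, collapse = ", ")))
    }
  }
  rows <- which(ev$true_labels == true_class & ev$predicted_labels == predicted_class)
  subset_image_table(ev$table, rows)
}

#' Write metrics to JSON
#'
#' All metric fields plus the learner hyperparameters, fold count and seed,
#' so a metrics report alone identifies the run that produced it.
#'
#' @param metrics A `classification_metrics`.
#' @param path Output JSON path.
#' @param ev Optional `cv_result` supplying hyperparameters/fold/seed.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path, ev = NULL) {
  obj <- list(CA = metrics$CA, F1 = metrics$F1, F1_macro = metrics$F1_macro,
              F1_weighted = metrics$F1_weighted,
              F1_per_class = as.list(metrics$F1_per_class),
              AUC_macro_ovr = metrics$AUC_macro_ovr, n = metrics$n)
  if (!is.null(ev)) {
    obj$folds <- ev$k
    obj$seed <- ev$seed
    obj$learner <- ev$learner
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a confusion matrix to CSV
#'
#' Square labeled matrix, rows = true class, columns = predicted class.
#'
#' @param cm A `confusion_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}
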