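# Cross-validated SVM evaluation and wrapper forward feature selection.
# The selection criterion is the same k-fold CV accuracy that is reported,
# reproducing the single-loop protocol; selection_generalization() offers an
# unbiased nested estimate for comparison.

# Stratified fold assignment, deterministic given the seed.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  local_seed(seed, {
    for (g in unique(labels)) {
      idx <- which(labels == g)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Cross-validated SVM evaluation of a feature subset
#'
#' Stratified k-fold cross-validation: within each training fold the selected
#' features are standardized (train-fold mean/SD only, applied to the test
#' fold), an SVM (`e1071::svm`, C = 1; RBF gamma = 1 / (p * mean feature
#' variance) computed on the standardized training block) is fitted, and the
#' pooled out-of-fold predictions give the confusion counts. The case group is
#' the positive class for sensitivity.
#'
#' @param X A `feature_matrix` (see [build_feature_matrix()]).
#' @param feature_ids Non-empty subset of `X$feature_ids`.
#' @param kernel `"rbf"` or `"linear"`.
#' @param k_folds Number of folds (default 10).
#' @param seed Seed for the stratified fold assignment.
#' @param cost SVM cost parameter C.
#' @param folds Optional precomputed fold assignment (overrides `seed`).
#' @return A `classifier_eval`: accuracy, sensitivity, specificity, confusion
#'   counts (TP, TN, FP, FN), kernel, folds.
#' @export
cv_evaluate <- function(X, feature_ids, kernel = c("rbf", "linear"),
                        k_folds = 10, seed = 1L, cost = 1, folds = NULL) {
  kernel <- match.arg(kernel)
  if (length(feature_ids) == 0) stop_erpica("empty feature subset")
  missing <- setdiff(feature_ids, X$feature_ids)
  if (length(missing)) {
    stop_erpica("unknown feature id(s): ", paste(missing, collapse = ", "))
  }
  y <- factor(X$group_labels, levels = c("control", "case"))
  if (nlevels(droplevels(y)) < 2) stop_erpica("need both classes present")
  if (min(table(y)) < 2) stop_erpica("need at least 2 subjects per class")
  V <- X$values[, feature_ids, drop = FALSE]
  if (is.null(folds)) folds <- stratified_folds(y, k_folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  svm_kernel <- if (kernel == "rbf") "radial" else "linear"
  for (f in sort(unique(folds))) {
    tr <- folds != f
    mu <- colMeans(V[tr, , drop = FALSE])
    sg <- apply(V[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Ztr <- sweep(sweep(V[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(V[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    gamma <- 1 / (ncol(Ztr) * max(mean(apply(Ztr, 2, stats::var)), 1e-12))
    fit <- e1071::svm(Ztr, y[tr], kernel = svm_kernel, cost = cost,
                      gamma = gamma, scale = FALSE)
    pred[!tr] <- stats::predict(fit, Zte)
  }
  tp <- sum(pred == "case" & y == "case")
  tn <- sum(pred == "control" & y == "control")
  fp <- sum(pred == "case" & y == "control")
  fn <- sum(pred == "control" & y == "case")
  structure(list(
    accuracy = (tp + tn) / length(y),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    TP = tp, TN = tn, FP = fp, FN = fn,
    kernel = kernel, k_folds = length(unique(folds)), folds = folds,
    predictions = pred
  ), class = "classifier_eval")
}

#' Classification metrics from confusion counts
#'
#' Closed-form accuracy, sensitivity and specificity from TP/TN/FP/FN, with
#' the case group as the positive class.
#'
#' @param TP,TN,FP,FN Confusion counts.
#' @return A `classifier_eval` (without fold information).
#' @export
eval_from_confusion <- function(TP, TN, FP, FN) {
  structure(list(
    accuracy = (TP + TN) / (TP + TN + FP + FN),
    sensitivity = TP / (TP + FN),
    specificity = TN / (TN + FP),
    TP = TP, TN = TN, FP = FP, FN = FN,
    kernel = NA_character_, k_folds = NA_integer_
  ), class = "classifier_eval")
}

#' Wrapper forward feature selection
#'
#' Greedy selection: at each of M steps, every remaining candidate is scored
#' by the cross-validated accuracy of the augmented subset ([cv_evaluate()]
#' with a fold assignment fixed once from `seed`), and the best is added (ties
#' broken to the lowest feature index). Cost is at most N x M evaluations.
#'
#' @param X A `feature_matrix`.
#' @param M Number of features to select (`0 <= M <= N`).
#' @param kernel,k_folds,seed,cost Passed to [cv_evaluate()].
#' @param verbose Print each selection step.
#' @return A `selection_result`: `selected` ids (in selection order),
#'   `cv_accuracy_trace`, `fold_assignment`, kernel, seed, number of
#'   evaluations performed.
#' @export
forward_select <- function(X, M, kernel = c("rbf", "linear"), k_folds = 10,
                           seed = 1L, cost = 1, verbose = FALSE) {
  kernel <- match.arg(kernel)
  N <- length(X$feature_ids)
  if (M > N) stop_erpica("M (", M, ") exceeds the number of features (", N, ")")
  y <- factor(X$group_labels, levels = c("control", "case"))
  folds <- stratified_folds(y, k_folds, seed)
  selected <- character(0)
  trace <- numeric(0)
  n_evals <- 0L
  while (length(selected) < M) {
    candidates <- setdiff(X$feature_ids, selected)
    best_acc <- -Inf
    best_id <- NULL
    for (id in candidates) {   # feature order = index order, ties keep first
      ev <- cv_evaluate(X, c(selected, id), kernel = kernel, cost = cost,
                        folds = folds)
      n_evals <- n_evals + 1L
      if (ev$accuracy > best_acc) {
        best_acc <- ev$accuracy
        best_id <- id
      }
    }
    selected <- c(selected, best_id)
    trace <- c(trace, best_acc)
    if (verbose) {
      message(sprintf("step %d: + %s (CV accuracy %.3f)",
                      length(selected), best_id, best_acc))
    }
  }
  structure(list(
    selected = selected, cv_accuracy_trace = trace,
    fold_assignment = folds, kernel = kernel, seed = as.integer(seed),
    n_evaluations = n_evals
  ), class = "selection_result")
}

#' Nested-CV generalization estimate of forward selection
#'
#' Unlike the single-loop protocol (selection scored on the same folds that
#' are reported), this runs forward selection inside each outer training fold
#' and scores only the held-out outer fold, giving an approximately unbiased
#' accuracy estimate. Considerably more expensive; intended for small feature
#' sets.
#'
#' @param X A `feature_matrix`.
#' @param M Features selected inside each outer fold.
#' @param outer_folds,inner_folds Fold counts.
#' @param kernel,seed,cost As in [forward_select()].
#' @return A `classifier_eval` from the pooled outer-fold predictions.
#' @export
selection_generalization <- function(X, M, outer_folds = 5, inner_folds = 10,
                                     kernel = c("rbf", "linear"), seed = 1L,
                                     cost = 1) {
  kernel <- match.arg(kernel)
  y <- factor(X$group_labels, levels = c("control", "case"))
  ofold <- stratified_folds(y, outer_folds, seed + 1000L)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  svm_kernel <- if (kernel == "rbf") "radial" else "linear"
  for (f in sort(unique(ofold))) {
    tr <- ofold != f
    Xtr <- structure(list(values = X$values[tr, , drop = FALSE],
                          subject_ids = X$subject_ids[tr],
                          group_labels = X$group_labels[tr],
                          feature_ids = X$feature_ids, specs = X$specs),
                     class = "feature_matrix")
    sel <- forward_select(Xtr, M, kernel = kernel, k_folds = inner_folds,
                          seed = seed, cost = cost)
    V <- X$values[, sel$selected, drop = FALSE]
    mu <- colMeans(V[tr, , drop = FALSE])
    sg <- apply(V[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    Ztr <- sweep(sweep(V[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(V[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    gamma <- 1 / (ncol(Ztr) * max(mean(apply(Ztr, 2, stats::var)), 1e-12))
    fit <- e1071::svm(Ztr, y[tr], kernel = svm_kernel, cost = cost,
                      gamma = gamma, scale = FALSE)
    pred[!tr] <- stats::predict(fit, Zte)
  }
  tp <- sum(pred == "case" & y == "case")
  tn <- sum(pred == "control" & y == "control")
  fp <- sum(pred == "case" & y == "control")
  fn <- sum(pred == "control" & y == "case")
  eval_from_confusion(tp, tn, fp, fn)
}
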