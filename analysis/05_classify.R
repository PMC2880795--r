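#!/usr/bin/env Rscript
# Stage 5 — forward-selected SVM classification.
#
# Greedy wrapper selection of 5 features under stratified 10-fold CV with an
# RBF-kernel SVM, then evaluation of the selected panel with both kernels.

library(erpica)

fm <- read_feature_matrix("scratch/feature_matrix.csv")

sel <- forward_select(fm, M = 5, kernel = "rbf", k_folds = 10, seed = 3,
                      verbose = TRUE)
ev_rbf <- cv_evaluate(fm, sel$selected, kernel = "rbf",
                      folds = sel$fold_assignment)
ev_lin <- cv_evaluate(fm, sel$selected, kernel = "linear",
                      folds = sel$fold_assignment)

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(list(
  selected = sel$selected,
  cv_accuracy_trace = sel$cv_accuracy_trace,
  rbf = list(accuracy = ev_rbf$accuracy, sensitivity = ev_rbf$sensitivity,
             specificity = ev_rbf$specificity),
  linear = list(accuracy = ev_lin$accuracy)
), "results/classification.json", auto_unbox = TRUE, digits = NA)

cat("Selected features (in order):\n")
for (i in seq_along(sel$selected)) {
  cat(sprintf("  %d. %s  (CV accuracy %.3f)\n", i, sel$selected[i],
              sel$cv_accuracy_trace[i]))
}
cat(sprintf("RBF:    accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
            100 * ev_rbf$accuracy, 100 * ev_rbf$sensitivity,
            100 * ev_rbf$specificity))
cat(sprintf("Linear: accuracy %.1f%%\n", 100 * ev_lin$accuracy))
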