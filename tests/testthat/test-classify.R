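make_fm <- function(values, groups) {
  structure(list(
    values = values,
    subject_ids = rownames(values) %||% paste0("s", seq_len(nrow(values))),
    group_labels = groups,
    feature_ids = colnames(values),
    specs = NULL
  ), class = "feature_matrix")
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("a perfectly separable 1-D feature gives accuracy 1 with both kernels", {
  v <- matrix(c(rnorm(10, -5, .3), rnorm(10, 5, .3)), ncol = 1,
              dimnames = list(NULL, "f1"))
  fm <- make_fm(v, rep(c("control", "case"), each = 10))
  for (k in c("rbf", "linear")) {
    ev <- cv_evaluate(fm, "f1", kernel = k, k_folds = 5, seed = 1)
    expect_equal(ev$accuracy, 1)
    expect_equal(ev$sensitivity, 1)
    expect_equal(ev$specificity, 1)
  }
})

test_that("pure-noise features give chance-level accuracy under the permutation null", {
  n_rep <- 50
  accs <- withr::with_seed(123, vapply(seq_len(n_rep), function(i) {
    v <- matrix(rnorm(40), ncol = 1, dimnames = list(NULL, "f1"))
    fm <- make_fm(v, sample(rep(c("control", "case"), each = 20)))
    cv_evaluate(fm, "f1", kernel = "rbf", k_folds = 5, seed = i)$accuracy
  }, numeric(1)))
  # mean accuracy 0.5; MC standard error of the mean ~ 0.011, band = 4.5 SE
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("metrics from confusion counts match the closed form", {
  ev <- eval_from_confusion(TP = 67, FN = 7, TN = 70, FP = 4)
  expect_equal(ev$sensitivity, 67 / 74, tolerance = 1e-12)   # ~0.905
  expect_equal(ev$specificity, 70 / 74, tolerance = 1e-12)   # ~0.946
  expect_equal(ev$accuracy, 137 / 148, tolerance = 1e-12)    # ~0.926
  expect_equal(round(ev$sensitivity, 2), 0.91)
  expect_equal(round(ev$specificity, 2), 0.95)
  expect_equal(round(ev$accuracy, 2), 0.93)
})

test_that("cv_evaluate rejects degenerate inputs and is deterministic", {
  v <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  fm_one <- make_fm(v, rep("case", 10))
  expect_error(cv_evaluate(fm_one, "a"), "both classes")
  fm <- make_fm(v, rep(c("control", "case"), each = 5))
  expect_error(cv_evaluate(fm, character(0)), "empty")
  expect_error(cv_evaluate(fm, "zzz"), "unknown feature")
  e1 <- cv_evaluate(fm, "a", k_folds = 5, seed = 9)
  e2 <- cv_evaluate(fm, "a", k_folds = 5, seed = 9)
  expect_identical(e1$predictions, e2$predictions)
})

test_that("forward selection finds the planted feature first and respects the budget", {
  set.seed(77)
  n <- 40
  groups <- rep(c("control", "case"), each = n / 2)
  noise <- matrix(rnorm(n * 50), n)
  signal <- ifelse(groups == "case", 4, -4) + rnorm(n, 0, .2)
  v <- cbind(noise[, 1:25], signal, noise[, 26:50])
  colnames(v) <- paste0("f", seq_len(ncol(v)))
  fm <- make_fm(v, groups)
  sel <- forward_select(fm, M = 2, kernel = "rbf", k_folds = 5, seed = 3)
  expect_equal(sel$selected[1], "f26")
  expect_length(sel$cv_accuracy_trace, 2)
  expect_lte(sel$n_evaluations, 2 * ncol(v))        # O(N*M) contract
  # trace step 1 is the max over all single-feature criteria
  single <- vapply(colnames(v)[c(1, 10, 26, 40)], function(id) {
    cv_evaluate(fm, id, kernel = "rbf", folds = sel$fold_assignment)$accuracy
  }, numeric(1))
  expect_gte(sel$cv_accuracy_trace[1], max(single))
})

test_that("forward selection edge cases: M = 0, M = N = 1, M > N", {
  v <- matrix(c(rnorm(6, -2), rnorm(6, 2)), ncol = 1,
              dimnames = list(NULL, "only"))
  fm <- make_fm(v, rep(c("control", "case"), each = 6))
  s0 <- forward_select(fm, 0, k_folds = 3)
  expect_length(s0$selected, 0)
  expect_length(s0$cv_accuracy_trace, 0)
  s1 <- forward_select(fm, 1, k_folds = 3, seed = 2)
  expect_equal(s1$selected, "only")
  expect_equal(s1$cv_accuracy_trace,
               cv_evaluate(fm, "only", k_folds = 3,
                           folds = s1$fold_assignment)$accuracy)
  expect_error(forward_select(fm, 2), "exceeds")
})

test_that("nested-CV estimate runs and stays near the single-loop value on strong signal", {
  set.seed(5)
  n <- 30
  groups <- rep(c("control", "case"), each = n / 2)
  v <- cbind(sig = ifelse(groups == "case", 3, -3) + rnorm(n, 0, .5),
             ns1 = rnorm(n), ns2 = rnorm(n))
  fm <- make_fm(v, groups)
  nest <- selection_generalization(fm, M = 1, outer_folds = 3,
                                   inner_folds = 3, kernel = "rbf", seed = 2)
  expect_gte(nest$accuracy, 0.9)
})
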