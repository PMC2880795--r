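test_that("summary t-test matches the raw-data pooled t-test exactly", {
  set.seed(42)
  for (i in 1:5) {
    a <- rnorm(30, 1, 2)
    b <- rnorm(25, 0, 1.5)
    ours <- ttest_from_summary(mean(a), sd(a), length(a),
                               mean(b), sd(b), length(b))
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("summary t-test handles identical and degenerate groups", {
  r <- ttest_from_summary(2, 1, 10, 2, 1, 10)
  expect_equal(r$t, 0)
  expect_equal(r$df, 18)
  r0 <- ttest_from_summary(3, 0, 5, 3, 0, 5)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_error(ttest_from_summary(3, 0, 5, 4, 0, 5), "infinite")
  expect_error(ttest_from_summary(1, 1, 1, 0, 1, 10), "n >= 2")
})

test_that("group swap negates t and preserves p", {
  a <- ttest_from_summary(4.51, 2.27, 74, 0.08, 0.28, 74)
  b <- ttest_from_summary(0.08, 0.28, 74, 4.51, 2.27, 74)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_equal(a$t, 16.67, tolerance = 5e-3)
  expect_equal(a$df, 146)
})

test_that("the shipped cohort table reproduces its published t statistics", {
  tab <- ttest_summary_table()
  expect_true(all(tab$df == 146))
  get_t <- function(v) tab$t[tab$variable == v]
  # printed values; residual differences stem from rounding of the table cells
  expect_equal(get_t("current_inattentive_symptoms"), 25.838, tolerance = 0.01)
  expect_equal(get_t("current_hyperactive_impulsive_symptoms"), 16.668,
               tolerance = 0.01)
  expect_equal(get_t("current_total_adhd_symptoms"), 26.940, tolerance = 0.01)
  expect_equal(get_t("bsi_general_severity_index"), 14.219, tolerance = 0.01)
  expect_equal(get_t("omission_errors_go"), 5.125, tolerance = 0.01)
  expect_equal(get_t("standard_error_mean_rt_ms"), 5.275, tolerance = 0.01)
})

test_that("pointwise t is zero for identical groups and flags a planted window", {
  toy <- fitted_toy_model()
  ds <- toy$dataset
  m <- toy$model
  # identical group data: copy control ERPs onto cases
  same <- ds
  ctrl <- ds$subjects$subject_id[ds$subjects$group == "control"]
  case <- ds$subjects$subject_id[ds$subjects$group == "case"]
  for (i in seq_along(case)) same$erps[[case[i]]] <- ds$erps[[ctrl[i]]]
  res0 <- ttest_pointwise(same, m, 1, m$channel_order[1])
  expect_true(all(res0$t == 0))
  expect_false(any(res0$significant))
  expect_true(all(res0$df == nrow(ds$subjects) - 2))
  # planted amplitude difference in 300-400 ms at high SNR
  cfg <- tiny_config(seed = 61, n = 20, noise = 0.3, jitter = 2)
  gt <- make_ground_truth(cfg, 7)
  ds2 <- simulate_dataset(gt, cfg)
  bump <- function(tms) 6 * exp(-(tms - 350)^2 / (2 * 20^2))
  m2 <- suppressWarnings(fit_infomax(concat_all(ds2), seed = 2))
  mt <- erpica:::greedy_match_columns(gt$topographies, m2$U_inv)
  ci <- mt$b[mt$a == 4]
  chan <- m2$channel_order[which.max(abs(m2$U_inv[, ci]))]
  chan_idx <- match(chan, ds2$channels)
  topo_w <- gt$topographies[chan_idx, 4]
  for (id in ds2$subjects$subject_id[ds2$subjects$group == "case"]) {
    e <- ds2$erps[[id]]$NOGO
    add <- gt$topographies[, 4, drop = FALSE] %*% t(bump(e$time_ms))
    ds2$erps[[id]]$NOGO$data <- e$data + add
  }
  res <- ttest_pointwise(ds2, m2, ci, chan)
  inside <- res$time_ms >= 320 & res$time_ms <= 380   # bump core (center 350, sd 20)
  expect_gt(mean(res$significant[inside]), 0.9)
  expect_lt(mean(res$significant[res$time_ms < 200]), 0.3)
})

test_that("pointwise mask frequency under the null is near alpha", {
  # identity model on 3 channels; 200 null datasets x 10 time points
  ch <- c("A", "B", "C")
  U <- diag(3); dimnames(U) <- list(paste0("IC", 1:3), ch)
  m <- structure(list(U = U, U_inv = t(U), channel_order = ch,
                      component_names = paste0("IC", 1:3)),
                 class = "mixing_model")
  tms <- seq(0, 36, by = 4)
  null_ds <- function() {
    ids <- sprintf("s%02d", 1:30)
    erps <- lapply(seq_along(ids), function(i) {
      d <- matrix(rnorm(3 * 10), 3, 10, dimnames = list(ch, NULL))
      list(NOGO = erpica:::new_subject_erp(d, tms, 250, ids[i],
                                  if (i <= 15) "control" else "case", "NOGO"))
    })
    names(erps) <- ids
    structure(list(erps = erps,
                   subjects = data.frame(subject_id = ids,
                                         group = rep(c("control", "case"),
                                                     each = 15)),
                   conditions = "NOGO", channels = ch, time_ms = tms,
                   sampling_rate_hz = 250), class = "erp_dataset")
  }
  n_sim <- 200
  hits <- withr::with_seed(99, vapply(seq_len(n_sim), function(i) {
    mean(ttest_pointwise(null_ds(), m, 1, "A")$significant)
  }, numeric(1)))
  se <- sqrt(0.05 * 0.95 / (n_sim * 10))
  expect_lt(abs(mean(hits) - 0.05), 4 * se)
})
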