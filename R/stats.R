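# Pooled-variance Student t comparisons: from printed summary statistics,
# and pointwise along component time courses with an uncorrected p < alpha
# significance mask.

#' Two-sample t-test from summary statistics
#'
#' Classic pooled-variance Student t from (mean, sd, n) per group:
#' `t = (m1 - m2) / sqrt(sp2 * (1/n1 + 1/n2))` with
#' `sp2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)` and
#' `df = n1 + n2 - 2`. Matches a raw-data `t.test(var.equal = TRUE)` exactly
#' when the summaries are computed from the raw samples.
#'
#' @param mean1,sd1,n1 First group's summary statistics.
#' @param mean2,sd2,n2 Second group's summary statistics.
#' @return A `ttest_result`: `t`, `df`, two-sided `p`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop_erpica("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0) stop_erpica("sd must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) {
      return(structure(list(t = 0, df = df, p = 1), class = "ttest_result"))
    }
    stop_erpica("zero pooled variance with unequal means: t is infinite")
  }
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(list(t = tval, df = df,
                 p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE)),
            class = "ttest_result")
}

#' Reference cohort summary table
#'
#' The published psychometric and task-performance summary statistics (mean,
#' sd, n = 74 per group) of the adult cohort whose design the synthetic
#' benchmark emulates, shipped as a worked-example input for
#' [ttest_from_summary()].
#'
#' @return Data frame with columns `variable`, `mean_case`, `sd_case`,
#'   `mean_control`, `sd_control`, `n_case`, `n_control`.
#' @export
cohort_summary_table <- function() {
  path <- system.file("extdata", "cohort_summary_stats.csv", package = "erpica")
  if (path == "") path <- file.path("inst", "extdata", "cohort_summary_stats.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Pooled t-tests for every row of a summary table
#'
#' @param table Data frame in the layout of [cohort_summary_table()].
#' @return The table with `t`, `df`, `p` columns appended.
#' @export
ttest_summary_table <- function(table = cohort_summary_table()) {
  res <- lapply(seq_len(nrow(table)), function(i) {
    ttest_from_summary(table$mean_case[i], table$sd_case[i], table$n_case[i],
                       table$mean_control[i], table$sd_control[i],
                       table$n_control[i])
  })
  table$t <- vapply(res, `[[`, 0, "t")
  table$df <- vapply(res, `[[`, 0, "df")
  table$p <- vapply(res, `[[`, 0, "p")
  table
}

#' Pointwise group comparison of a component time course
#'
#' At every time sample, the component's projection value at `channel` is
#' compared between groups with a pooled two-sample t-test; the mask flags
#' samples with `p < alpha`. No multiple-comparison correction is applied.
#'
#' @param dataset An `erp_dataset` with both groups present.
#' @param model A `mixing_model`.
#' @param component Component index in the model.
#' @param channel Channel name.
#' @param condition Condition label (default `"NOGO"`).
#' @param alpha Significance level for the mask (default 0.05).
#' @return Data frame with columns `time_ms`, `t`, `df`, `p`, `significant`.
#' @export
ttest_pointwise <- function(dataset, model, component, channel,
                            condition = "NOGO", alpha = 0.05) {
  groups <- dataset$subjects$group
  if (length(unique(groups)) < 2) stop_erpica("both groups must be present")
  ri <- match(channel, model$channel_order)
  if (is.na(ri)) stop_erpica("unknown channel ", channel)
  ids <- dataset$subjects$subject_id
  tc <- vapply(ids, function(id) {
    erp <- dataset$erps[[id]][[condition]]
    if (is.null(erp)) stop_erpica("subject ", id, " missing condition ", condition)
    project_component(model, component, erp$data)[ri, ]
  }, numeric(length(dataset$time_ms)))
  a <- tc[, groups == "case", drop = FALSE]
  b <- tc[, groups == "control", drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2) stop_erpica("need >= 2 subjects per group")
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  tval <- ifelse(sp2 == 0 & m1 == m2, 0,
                 (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2)))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  data.frame(time_ms = dataset$time_ms, t = tval, df = df, p = p,
             significant = p < alpha)
}
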