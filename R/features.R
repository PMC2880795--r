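# Sliding-window extremum features over component time courses: template
# enumeration, scalar extraction, and assembly of the subjects x features
# matrix that feeds the classifier.

#' Feature template
#'
#' A parametric family of sliding-window extremum features: windows of size
#' `window_ms` start at `start_ms` and advance by `step_ms` while the window
#' still fits (`t0 + window_ms <= end_ms`); each window yields one feature per
#' (extremum, return-type) choice.
#'
#' @param start_ms,end_ms Search range in ms (start < end).
#' @param window_ms Window size in ms, `0 < window_ms <= end_ms - start_ms`.
#' @param step_ms Positive step between window starts in ms.
#' @param extremum `"min"` or `"max"`.
#' @param returns `"amplitude"` or `"latency"`.
#' @return A `feature_template` object.
#' @export
feature_template <- function(start_ms, end_ms, window_ms, step_ms,
                             extremum = c("min", "max"),
                             returns = c("amplitude", "latency")) {
  extremum <- match.arg(extremum)
  returns <- match.arg(returns)
  if (!(start_ms < end_ms)) stop_erpica("start_ms must be < end_ms")
  if (!(window_ms > 0 && window_ms <= end_ms - start_ms)) {
    stop_erpica("window_ms must satisfy 0 < window_ms <= end_ms - start_ms")
  }
  if (step_ms <= 0) stop_erpica("step_ms must be > 0")
  structure(list(start_ms = start_ms, end_ms = end_ms, window_ms = window_ms,
                 step_ms = step_ms, extremum = extremum, returns = returns),
            class = "feature_template")
}

#' The reference template grid
#'
#' Templates over 0-600 ms with window sizes 100 ms plus/minus 25% and 50%
#' (50, 75, 100, 125, 150 ms), 4 ms steps, both extremum types and both return
#' types — the full automatic feature family; over seven components it
#' enumerates 17,584 concrete features.
#'
#' @param start_ms,end_ms Range (defaults 0 and 600).
#' @param windows_ms Window sizes (default `c(50, 75, 100, 125, 150)`).
#' @param step_ms Step (default 4).
#' @param extrema,returns Types crossed into the grid.
#' @return List of `feature_template` objects.
#' @export
reference_templates <- function(start_ms = 0, end_ms = 600,
                                windows_ms = c(50, 75, 100, 125, 150),
                                step_ms = 4,
                                extrema = c("min", "max"),
                                returns = c("amplitude", "latency")) {
  out <- list()
  for (w in windows_ms) for (ex in extrema) for (re in returns) {
    out[[length(out) + 1L]] <- feature_template(start_ms, end_ms, w, step_ms,
                                                ex, re)
  }
  out
}

#' Enumerate concrete feature specifications from a template
#'
#' One row per (component, window position): windows start at `start_ms` and
#' advance by `step_ms` while `t0 + window_ms <= end_ms`, giving
#' `floor((end - window - start)/step) + 1` windows per component. Ordering is
#' deterministic: component order, then window start.
#'
#' @param template A [feature_template()] or a list of them.
#' @param components Character vector of component names.
#' @param channel_map Optional named map component -> channel, stored in the
#'   specs and used in the feature id.
#' @return Data frame with columns `component`, `channel`, `t0_ms`, `t1_ms`,
#'   `extremum`, `returns`, `id`.
#' @export
enumerate_features <- function(template, components, channel_map = NULL) {
  if (inherits(template, "feature_template")) template <- list(template)
  rows <- list()
  for (comp in components) {
    chan <- if (!is.null(channel_map)) channel_map[[comp]] else NA_character_
    for (tp in template) {
      t0 <- seq(tp$start_ms, tp$end_ms - tp$window_ms, by = tp$step_ms)
      if (length(t0) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp,
        channel = chan %||% NA_character_,
        t0_ms = t0, t1_ms = t0 + tp$window_ms,
        extremum = tp$extremum, returns = tp$returns,
        stringsAsFactors = FALSE
      )
    }
  }
  specs <- do.call(rbind, rows)
  if (is.null(specs)) {
    specs <- data.frame(component = character(), channel = character(),
                        t0_ms = numeric(), t1_ms = numeric(),
                        extremum = character(), returns = character(),
                        stringsAsFactors = FALSE)
  }
  tag <- ifelse(is.na(specs$channel), specs$component,
                paste(specs$component, specs$channel, sep = "_"))
  specs$id <- sprintf("%s_%s_%s_%g_%g", tag, specs$extremum, specs$returns,
                      specs$t0_ms, specs$t1_ms)
  specs
}

#' Extract one extremum feature from a time course
#'
#' Locates the minimum or maximum over the samples with `t0 <= t <= t1`
#' (closed interval) and returns either the extremal value (amplitude, in the
#' waveform's units) or its time (latency, ms relative to stimulus onset).
#' Ties are broken to the earliest sample.
#'
#' @param spec One-row data frame (or list) with `t0_ms`, `t1_ms`, `extremum`,
#'   `returns`.
#' @param timecourse Numeric waveform.
#' @param time_ms Time axis (ms) of the waveform, same length.
#' @return Scalar feature value.
#' @export
extract_feature <- function(spec, timecourse, time_ms) {
  if (spec$t0_ms < min(time_ms) - 1e-9 || spec$t1_ms > max(time_ms) + 1e-9) {
    stop_erpica("feature window [", spec$t0_ms, ", ", spec$t1_ms,
                "] outside the time course span")
  }
  in_win <- which(time_ms >= spec$t0_ms - 1e-9 & time_ms <= spec$t1_ms + 1e-9)
  seg <- timecourse[in_win]
  pos <- if (spec$extremum == "min") which.min(seg) else which.max(seg)
  if (spec$returns == "amplitude") seg[pos] else time_ms[in_win[pos]]
}

#' Build the subjects x features matrix
#'
#' For each subject, each component named in `specs` is projected out of the
#' subject's ERP for that component's condition via its spatial filter, the
#' time course at the mapped channel is taken, and every spec is extracted.
#' Components are addressed by name in the fitted model (or via `model_map`
#' when spec components are aliases of model components).
#'
#' @param dataset An `erp_dataset`.
#' @param model A `mixing_model` (or named list of models keyed by condition;
#'   the model for each component's condition is used).
#' @param specs Data frame from [enumerate_features()].
#' @param channel_map Named list/vector component -> channel name; overrides
#'   channels in `specs`.
#' @param component_conditions Named list/vector component -> condition label;
#'   unlisted components default to `"NOGO"`.
#' @return A `feature_matrix`: numeric `values` (subjects x features, dimnames
#'   set), `subject_ids`, `group_labels`, `feature_ids`, and the spec table.
#' @export
build_feature_matrix <- function(dataset, model, specs, channel_map,
                                 component_conditions = NULL) {
  comps <- unique(specs$component)
  missing_ch <- setdiff(comps, names(channel_map))
  if (length(missing_ch)) {
    stop_erpica("no channel mapped for component(s): ",
                paste(missing_ch, collapse = ", "))
  }
  per_condition <- !inherits(model, "mixing_model")
  cond_of <- function(comp) {
    (component_conditions[[comp]] %||% "NOGO")
  }
  model_of <- function(cond) {
    if (per_condition) {
      m <- model[[cond]]
      if (is.null(m)) stop_erpica("no fitted model for condition ", cond)
      m
    } else model
  }
  ids <- dataset$subjects$subject_id
  values <- matrix(NA_real_, length(ids), nrow(specs),
                   dimnames = list(ids, specs$id))
  tms <- dataset$time_ms
  for (s in seq_along(ids)) {
    id <- ids[s]
    for (comp in comps) {
      cond <- cond_of(comp)
      erp <- dataset$erps[[id]][[cond]]
      if (is.null(erp)) {
        stop_erpica("subject ", id, " is missing condition ", cond)
      }
      m <- model_of(cond)
      ci <- match(comp, m$component_names)
      if (is.na(ci)) stop_erpica("component ", comp, " not in fitted model")
      chan <- channel_map[[comp]]
      ri <- match(chan, m$channel_order)
      if (is.na(ri)) stop_erpica("channel ", chan, " not in model montage")
      tc <- project_component(m, ci, erp$data)[ri, ]
      rows <- which(specs$component == comp)
      for (k in rows) {
        values[s, k] <- extract_feature(specs[k, ], tc, tms)
      }
    }
  }
  structure(list(
    values = values,
    subject_ids = ids,
    group_labels = dataset$subjects$group,
    feature_ids = specs$id,
    specs = specs
  ), class = "feature_matrix")
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  cbind(data.frame(subject_id = x$subject_ids, group = x$group_labels,
                   stringsAsFactors = FALSE),
        as.data.frame(x$values))
}
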