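# File round-trips in the package's native plain-text convention:
# one TSV per subject x condition (column 1 time_ms, then channels in the
# canonical order) with a JSON sidecar of metadata, plus a dataset manifest;
# mixing models and reports as JSON.

#' Write an ERP dataset to a directory
#'
#' One `<subject>_<condition>.tsv` per averaged ERP (column `time_ms` then the
#' channels in canonical order), a matching `.json` sidecar (subject_id,
#' group, condition, sampling_rate_hz), and a `manifest.json` with the channel
#' order and subject table. Values round-trip to better than 1e-9.
#'
#' @param dataset An `erp_dataset`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (id in dataset$subjects$subject_id) {
    for (cond in dataset$conditions) {
      erp <- dataset$erps[[id]][[cond]]
      stem <- file.path(path, paste0(id, "_", cond))
      tab <- data.frame(time_ms = erp$time_ms, t(erp$data),
                        check.names = FALSE)
      utils::write.table(format(tab, digits = 15, scientific = FALSE,
                                trim = TRUE),
                         paste0(stem, ".tsv"), sep = "\t", row.names = FALSE,
                         quote = FALSE)
      jsonlite::write_json(list(subject_id = erp$subject_id, group = erp$group,
                                condition = cond,
                                sampling_rate_hz = erp$sampling_rate_hz),
                           paste0(stem, ".json"), auto_unbox = TRUE)
    }
  }
  jsonlite::write_json(list(channels = dataset$channels,
                            conditions = dataset$conditions,
                            sampling_rate_hz = dataset$sampling_rate_hz,
                            subjects = dataset$subjects),
                       file.path(path, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an ERP dataset written by [write_dataset()]
#'
#' Validates channel count and order against the manifest, requires a sidecar
#' with a `group` entry for every ERP file, and checks the time axis for a
#' uniform step.
#'
#' @param path Directory containing `manifest.json` and TSV/JSON pairs.
#' @return An `erp_dataset`.
#' @export
read_dataset <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop_erpica("missing manifest.json in ", path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  channels <- mf$channels
  erps <- list()
  time_ms <- NULL
  for (id in mf$subjects$subject_id) {
    per_cond <- list()
    for (cond in mf$conditions) {
      stem <- file.path(path, paste0(id, "_", cond))
      side_path <- paste0(stem, ".json")
      if (!file.exists(side_path)) {
        stop_erpica("missing sidecar ", side_path)
      }
      side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
      if (is.null(side$group)) {
        stop_erpica("sidecar ", side_path, " lacks a 'group' entry")
      }
      tab <- utils::read.table(paste0(stem, ".tsv"), sep = "\t", header = TRUE,
                               check.names = FALSE)
      got <- setdiff(names(tab), "time_ms")
      if (length(got) != length(channels)) {
        stop_erpica("channel-count mismatch in ", stem, ".tsv: expected ",
                    length(channels), ", found ", length(got))
      }
      if (!identical(got, channels)) {
        stop_erpica("channel-order mismatch in ", stem, ".tsv")
      }
      tms <- tab$time_ms
      if (length(tms) > 2 &&
          max(abs(diff(tms) - diff(tms)[1])) > 1e-6) {
        stop_erpica("non-uniform time axis in ", stem, ".tsv")
      }
      time_ms <- tms
      dat <- t(as.matrix(tab[, channels, drop = FALSE]))
      per_cond[[cond]] <- new_subject_erp(dat, tms, side$sampling_rate_hz,
                                          side$subject_id, side$group, cond)
    }
    erps[[id]] <- per_cond
  }
  structure(list(
    erps = erps,
    subjects = mf$subjects,
    conditions = mf$conditions,
    channels = channels,
    time_ms = time_ms,
    sampling_rate_hz = mf$sampling_rate_hz,
    ground_truth = NULL,
    config = NULL
  ), class = "erp_dataset")
}

#' Write / read a fitted mixing model as JSON
#'
#' Stores the unmixing matrix row-major with channel order, component names,
#' explained power and fit metadata.
#'
#' @param model A `mixing_model`.
#' @param path JSON file path.
#' @return `path` invisibly, or the restored `mixing_model`.
#' @export
write_mixing_model <- function(model, path) {
  jsonlite::write_json(list(
    channel_order = model$channel_order,
    component_names = model$component_names,
    U = apply(unname(model$U), 1, identity, simplify = FALSE),
    explained_power = unname(model$explained_power),
    signal_rank = model$signal_rank,
    iterations = model$iterations,
    converged = model$converged,
    seed = model$seed,
    sign_convention = model$sign_convention
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mixing_model
#' @export
read_mixing_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  U <- if (is.list(m$U)) do.call(rbind, m$U) else m$U
  U_inv <- solve(U)
  dimnames(U) <- list(m$component_names, m$channel_order)
  dimnames(U_inv) <- list(m$channel_order, m$component_names)
  structure(list(
    U = U, U_inv = U_inv, channel_order = m$channel_order,
    component_names = m$component_names,
    explained_power = m$explained_power,
    signal_rank = m$signal_rank, iterations = m$iterations,
    converged = m$converged, seed = m$seed,
    sign_convention = m$sign_convention
  ), class = "mixing_model")
}

#' Write / read a feature matrix as CSV
#'
#' Columns: `subject_id`, `group`, then one column per feature id.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV file path.
#' @return `path` invisibly, or the restored `feature_matrix` (without specs).
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.csv(as.data.frame(fm), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, setdiff(names(tab), c("subject_id", "group")),
                          drop = FALSE])
  rownames(values) <- tab$subject_id
  structure(list(
    values = values,
    subject_ids = tab$subject_id,
    group_labels = tab$group,
    feature_ids = colnames(values),
    specs = NULL
  ), class = "feature_matrix")
}
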