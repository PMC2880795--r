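# Epoch-level cleaning: average re-referencing, artifact rejection by the
# amplitude and band-limited rules, epoch averaging, and projection-based
# component removal.

#' Average re-referencing
#'
#' Subtracts the instantaneous mean over channels from every time point, so
#' every column of the result sums to zero. Linear and idempotent.
#'
#' @param data C x T numeric matrix (channels x time).
#' @return Matrix of the same shape with zero channel mean at every sample.
#' @export
rereference_average <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 2) {
    stop_erpica("average reference needs at least 2 channels")
  }
  sweep(data, 2, colMeans(data))
}

# Zero-phase Butterworth filtering of each channel (row) of an epoch.
filter_rows <- function(e, filt) {
  t(apply(e, 1, function(x) signal::filtfilt(filt, x)))
}

#' Mark artifact epochs
#'
#' An epoch is rejected iff any channel violates any of three rules: raw
#' absolute amplitude strictly greater than `amp_uv` (default 100 microvolt);
#' maximum absolute value of the zero-phase Butterworth 20-35 Hz band-passed
#' trace strictly greater than `fast_uv` (default 35); maximum absolute value
#' of the 1 Hz low-passed trace strictly greater than `slow_uv` (default 50).
#' Values exactly at a threshold are kept. Reason codes record which rules
#' fired for each rejected epoch.
#'
#' @param epochs An `epoch_set` (see [simulate_artifact_epochs()]).
#' @param amp_uv,fast_uv,slow_uv Thresholds in microvolt.
#' @param fast_band Band edges in Hz for the fast rule.
#' @param slow_hz Low-pass cutoff in Hz for the slow rule.
#' @return The epoch set with `rejected` (logical) and `reasons` filled in.
#' @export
reject_epochs <- function(epochs, amp_uv = 100, fast_uv = 35, slow_uv = 50,
                          fast_band = c(20, 35), slow_hz = 1) {
  fs <- epochs$sampling_rate_hz
  if (fs / 2 <= max(fast_band)) {
    stop_erpica("sampling rate too low to resolve the ", fast_band[1], "-",
                fast_band[2], " Hz band")
  }
  n <- length(epochs$epochs)
  if (n == 0) return(epochs)
  bp <- signal::butter(2, fast_band / (fs / 2), type = "pass")   # order 4 overall
  lp <- signal::butter(4, slow_hz / (fs / 2), type = "low")
  rejected <- logical(n)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    e <- epochs$epochs[[i]]
    why <- character(0)
    if (max(abs(e)) > amp_uv) why <- c(why, "amplitude")
    if (max(abs(filter_rows(e, bp))) > fast_uv) why <- c(why, "fast")
    if (max(abs(filter_rows(e, lp))) > slow_uv) why <- c(why, "slow")
    rejected[i] <- length(why) > 0
    reasons[[i]] <- why
  }
  epochs$rejected <- rejected
  epochs$reasons <- reasons
  epochs
}

#' Average epochs into an ERP
#'
#' Element-wise mean over epochs; with `mask_aware = TRUE` (default) rejected
#' epochs are excluded. Averaging N noisy copies of a template shrinks the
#' residual noise SD by a factor of about sqrt(N).
#'
#' @param epochs An `epoch_set`.
#' @param mask_aware Use the rejection mask if present.
#' @return C x T matrix.
#' @export
average_epochs <- function(epochs, mask_aware = TRUE) {
  keep <- seq_along(epochs$epochs)
  if (mask_aware && !anyNA(epochs$rejected)) {
    keep <- which(!epochs$rejected)
  }
  if (length(keep) == 0) {
    stop_erpica("all epochs rejected: subject unusable")
  }
  Reduce(`+`, epochs$epochs[keep]) / length(keep)
}

#' Remove components from an ERP by spatial-filter projection
#'
#' Returns `(I - sum of F_i) %*% P` for the spatial filters `F_i` of the given
#' component indices — the algebraic equivalent of zeroing those components'
#' activation curves and back-projecting. Removing every component of a square
#' model yields (numerically) zero; removing none returns `P` unchanged.
#'
#' @param P C x T matrix.
#' @param model A `mixing_model` from [fit_infomax()].
#' @param indices Integer component indices to remove.
#' @return C x T matrix with the selected components' scalp contributions
#'   subtracted.
#' @export
remove_components <- function(P, model, indices) {
  if (length(indices) == 0) return(P)
  if (any(indices < 1 | indices > ncol(model$U_inv))) {
    stop_erpica("component index out of range")
  }
  Fsum <- Reduce(`+`, lapply(indices, function(i) spatial_filter(model, i)))
  P - Fsum %*% P
}
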