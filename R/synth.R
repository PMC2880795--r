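# Synthetic ERP generator: ground-truth source topographies and waveforms,
# per-subject averaged ERPs with group latency shifts, and raw artifact-bearing
# epochs for testing the rejection rules.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic ERP study: cohort size, montage,
#' sampling, group effects and noise. The defaults emulate the study design the
#' pipeline targets: two groups of 74 subjects, 19 channels sampled at 250 Hz,
#' 600 ms epochs locked to the second stimulus of a GO/NOGO pair.
#'
#' @param n_per_group Subjects per group (cases and controls), at least 2.
#' @param channels Ordered channel names; default [erp_channels()].
#' @param sampling_rate_hz Sampling rate in Hz (default 250).
#' @param t_max_ms Epoch end in ms; the time axis runs 0..`t_max_ms` inclusive.
#' @param group_latency_shift_ms Per-source latency shift (ms) applied to the
#'   case group; scalar recycled over sources.
#' @param group_amplitude_scale Per-source multiplicative amplitude factor for
#'   the case group; scalar recycled.
#' @param subject_latency_jitter_sd_ms SD (ms) of the per-subject, per-source
#'   Gaussian latency jitter shared by both groups.
#' @param subject_amplitude_jitter_sdlog SD of the log-normal per-subject,
#'   per-source amplitude scale (default 0.3). Real ERP amplitudes vary
#'   substantially across individuals; without this variability, fixed-window
#'   amplitude features would pick up a planted latency shift as cleanly as
#'   latency features do, which averaged human ERPs do not support.
#' @param noise_sd_uv SD (microvolt) of i.i.d. Gaussian sensor noise added to
#'   each averaged ERP sample.
#' @param seed Integer master seed; identical config + seed gives bit-identical
#'   datasets.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 74,
                       channels = erp_channels(),
                       sampling_rate_hz = 250,
                       t_max_ms = 600,
                       group_latency_shift_ms = 0,
                       group_amplitude_scale = 1,
                       subject_latency_jitter_sd_ms = 4,
                       subject_amplitude_jitter_sdlog = 0.3,
                       noise_sd_uv = 0.5,
                       seed = 1L) {
  if (n_per_group < 2) stop_erpica("n_per_group must be >= 2")
  if (sampling_rate_hz <= 0) stop_erpica("sampling_rate_hz must be > 0")
  if (noise_sd_uv < 0) stop_erpica("noise_sd_uv must be >= 0")
  if (subject_latency_jitter_sd_ms < 0) stop_erpica("jitter sd must be >= 0")
  if (subject_amplitude_jitter_sdlog < 0) stop_erpica("amplitude jitter sd must be >= 0")
  if (t_max_ms <= 0) stop_erpica("t_max_ms must be > 0")
  structure(list(
    n_per_group = as.integer(n_per_group),
    channels = channels,
    sampling_rate_hz = sampling_rate_hz,
    t_max_ms = t_max_ms,
    group_latency_shift_ms = group_latency_shift_ms,
    group_amplitude_scale = group_amplitude_scale,
    subject_latency_jitter_sd_ms = subject_latency_jitter_sd_ms,
    subject_amplitude_jitter_sdlog = subject_amplitude_jitter_sdlog,
    noise_sd_uv = noise_sd_uv,
    seed = as.integer(seed)
  ), class = "sim_config")
}

time_axis_ms <- function(config) {
  step <- 1000 / config$sampling_rate_hz
  seq(0, config$t_max_ms, by = step)
}

#' Construct a ground-truth source model
#'
#' Builds unit-norm, zero-channel-mean topography columns and per-source
#' waveforms (sums of Gaussian peaks/troughs with known centers), plus a map of
#' which sources are active in each task condition. Because every topography
#' column has zero channel mean, average re-referencing leaves the forward
#' model invariant, and because extremum latencies are analytic they can be
#' recovered exactly by downstream feature tests.
#'
#' @param topographies C x K numeric matrix; columns are source scalp patterns.
#' @param waveforms List of K data frames with columns `center_ms`, `sd_ms`,
#'   `amplitude_uv` (one row per Gaussian bump; zero rows = silent source).
#' @param condition_map Named list: condition label -> integer vector of active
#'   source indices.
#' @param source_names Optional source labels.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(topographies, waveforms, condition_map,
                         source_names = NULL) {
  topographies <- as.matrix(topographies)
  K <- ncol(topographies)
  if (length(waveforms) != K) stop_erpica("need one waveform per source")
  if (K > nrow(topographies)) {
    stop_erpica("rank error: more sources (", K, ") than channels (",
                nrow(topographies), ")")
  }
  # normalize: zero channel mean then unit Euclidean norm per column
  topographies <- sweep(topographies, 2, colMeans(topographies))
  nrm <- sqrt(colSums(topographies^2))
  if (any(nrm < 1e-12)) stop_erpica("degenerate (constant) topography column")
  topographies <- sweep(topographies, 2, nrm, "/")
  if (qr(topographies)$rank < K) {
    stop_erpica("rank error: topography matrix is column rank deficient")
  }
  if (is.null(source_names)) source_names <- paste0("S", seq_len(K))
  colnames(topographies) <- source_names
  trough <- vapply(waveforms, function(w) {
    if (nrow(w) == 0 || all(w$amplitude_uv >= 0)) return(NA_real_)
    w$center_ms[which.min(w$amplitude_uv)]
  }, numeric(1))
  peak <- vapply(waveforms, function(w) {
    if (nrow(w) == 0 || all(w$amplitude_uv <= 0)) return(NA_real_)
    w$center_ms[which.max(w$amplitude_uv)]
  }, numeric(1))
  structure(list(
    topographies = topographies,
    waveforms = waveforms,
    condition_map = condition_map,
    source_names = source_names,
    trough_latency_ms = stats::setNames(trough, source_names),
    peak_latency_ms = stats::setNames(peak, source_names)
  ), class = "ground_truth")
}

# Smooth focal scalp pattern centered on one electrode.
focal_topography <- function(channels, center, sigma) {
  xy <- channel_coordinates(channels)
  c0 <- xy[center, ]
  d2 <- (xy[, 1] - c0[1])^2 + (xy[, 2] - c0[2])^2
  exp(-d2 / (2 * sigma^2))
}

gauss_bumps <- function(...) {
  args <- list(...)
  data.frame(center_ms = vapply(args, `[[`, 0, 1),
             sd_ms = vapply(args, `[[`, 0, 2),
             amplitude_uv = vapply(args, `[[`, 0, 3))
}

#' Default ground truth for a simulation config
#'
#' The default `k_sources = 7` model mirrors the component families the
#' pipeline is designed around: three condition-independent sensory sources
#' (occipital and bilateral temporo-parietal), three executive sources active
#' in the NOGO condition (parietal, premotor, anterior midline), and one
#' novelty-specific source. Each source is a focal scalp pattern with a
#' waveform made of one to two Gaussian peaks/troughs at distinct latencies.
#'
#' @param config A [sim_config()].
#' @param k_sources Number of latent sources (must not exceed channel count).
#' @return A [ground_truth()] object.
#' @export
make_ground_truth <- function(config, k_sources = 7) {
  channels <- config$channels
  if (k_sources > length(channels)) {
    stop_erpica("rank error: k_sources (", k_sources,
                ") exceeds channel count (", length(channels), ")")
  }
  if (k_sources == 7 && identical(channels, erp_channels())) {
    # Focal patterns and bump latencies are spread so that source time courses
    # stay near-uncorrelated across subjects and conditions; ICA assumes
    # independent sources, and the generator honors that by construction.
    topo <- cbind(
      focal_topography(channels, "O1", 0.45) +
        0.6 * focal_topography(channels, "O2", 0.45),
      focal_topography(channels, "T5", 0.42),
      focal_topography(channels, "T6", 0.42),
      focal_topography(channels, "Pz", 0.48),
      focal_topography(channels, "C3", 0.38) +
        focal_topography(channels, "C4", 0.38),
      focal_topography(channels, "Fz", 0.45),
      focal_topography(channels, "Cz", 0.60)
    )
    # Amplitudes are chosen so deflections at each source's best channel are a
    # few microvolt (topography columns are unit-norm, so scalp amplitude is
    # roughly 0.5-0.6 of the source amplitude) — the scale of real averaged
    # ERP components relative to residual post-averaging noise.
    wf <- list(
      gauss_bumps(c(60, 15, 6.0), c(105, 20, -15.0)),    # occipital N1-like
      gauss_bumps(c(175, 20, -12.0)),                    # left TPJ N170-like
      gauss_bumps(c(250, 20, -12.0)),                    # right TPJ-like
      gauss_bumps(c(320, 25, 15.0), c(510, 25, -12.0)),  # parietal P3 + late trough
      gauss_bumps(c(385, 22, 12.0)),                     # premotor NOGO
      gauss_bumps(c(440, 20, -10.0)),                    # anterior midline late wave
      gauss_bumps(c(140, 16, -12.0), c(212, 22, 15.0))   # novelty (central)
    )
    cmap <- list(NOGO = 1:6, NOVEL = c(1L, 2L, 3L, 7L))
    nm <- c("occipital", "tpj_left", "tpj_right", "parietal",
            "premotor", "midline", "novelty")
    return(ground_truth(topo[, seq_len(k_sources), drop = FALSE], wf, cmap, nm))
  }
  # generic model: focal patterns spread over the montage, troughs spread in time
  centers <- channels[round(seq(1, length(channels), length.out = k_sources))]
  topo <- vapply(seq_len(k_sources), function(i) {
    focal_topography(channels, centers[i], 0.5 + 0.07 * (i %% 3))
  }, numeric(length(channels)))
  lat <- seq(120, max(130, config$t_max_ms - 120), length.out = k_sources)
  wf <- lapply(seq_len(k_sources), function(i) {
    gauss_bumps(c(lat[i], 25, if (i %% 2) -4 else 4))
  })
  cmap <- list(NOGO = seq_len(k_sources), NOVEL = seq_len(k_sources))
  ground_truth(topo, wf, cmap)
}

# Evaluate all source waveforms on a time axis with per-source latency shift
# (applied to the analytic Gaussian centers, so no wrap-around) and amplitude
# scaling. Returns K x T.
eval_waveforms <- function(gt, time_ms, shift_ms = 0, scale = 1,
                           active = NULL) {
  K <- length(gt$waveforms)
  shift_ms <- rep_len(shift_ms, K)
  scale <- rep_len(scale, K)
  if (is.null(active)) active <- seq_len(K)
  W <- matrix(0, K, length(time_ms))
  for (k in intersect(seq_len(K), active)) {
    w <- gt$waveforms[[k]]
    if (nrow(w) == 0) next
    acc <- numeric(length(time_ms))
    for (j in seq_len(nrow(w))) {
      acc <- acc + w$amplitude_uv[j] *
        exp(-(time_ms - w$center_ms[j] - shift_ms[k])^2 / (2 * w$sd_ms[j]^2))
    }
    W[k, ] <- scale[k] * acc
  }
  W
}

#' Simulate one subject's averaged ERP
#'
#' Forward model: `ERP = topographies %*% waveforms + noise`, where the case
#' group's waveform centers are shifted by `group_latency_shift_ms` and scaled
#' by `group_amplitude_scale`, every subject receives Gaussian latency jitter,
#' and the result is average-referenced (a no-op for the signal part, whose
#' topographies already have zero channel mean, but it projects the sensor
#' noise too, so channel means are exactly zero).
#'
#' @param gt A [ground_truth()].
#' @param config A [sim_config()].
#' @param group `"control"` or `"case"`.
#' @param subject_seed Integer seed for this subject's jitter and noise.
#' @param condition Condition label; must be a name of `gt$condition_map`.
#' @param subject_id Identifier stored in the result.
#' @return A `subject_erp` object: C x T `data` matrix (rownames = channels),
#'   `time_ms`, `sampling_rate_hz`, `subject_id`, `group`, `condition`.
#' @export
simulate_subject <- function(gt, config, group, subject_seed,
                             condition = "NOGO",
                             subject_id = paste0(group, "_", subject_seed)) {
  if (!group %in% c("control", "case")) {
    stop_erpica("group must be 'control' or 'case'")
  }
  if (!condition %in% names(gt$condition_map)) {
    stop_erpica("unknown condition '", condition, "'")
  }
  K <- length(gt$waveforms)
  tms <- time_axis_ms(config)
  subject_effects <- local_seed(subject_seed, list(
    jitter = stats::rnorm(K, 0, config$subject_latency_jitter_sd_ms),
    amp = exp(stats::rnorm(K, 0, config$subject_amplitude_jitter_sdlog))
  ))
  shift <- subject_effects$jitter
  scale <- subject_effects$amp
  if (group == "case") {
    shift <- shift + rep_len(config$group_latency_shift_ms, K)
    scale <- scale * rep_len(config$group_amplitude_scale, K)
  }
  if (any(abs(shift) > config$t_max_ms)) {
    stop_erpica("boundary error: latency shift exceeds epoch length")
  }
  active <- gt$condition_map[[condition]]
  W <- eval_waveforms(gt, tms, shift, scale, active)
  E <- gt$topographies %*% W
  if (config$noise_sd_uv > 0) {
    cond_idx <- match(condition, names(gt$condition_map))
    noise <- local_seed(subject_seed + 131L * cond_idx,
                        matrix(stats::rnorm(length(E), 0, config$noise_sd_uv),
                               nrow(E), ncol(E)))
    E <- E + noise
  }
  E <- rereference_average(E)
  rownames(E) <- config$channels
  new_subject_erp(E, tms, config$sampling_rate_hz, subject_id, group, condition)
}

new_subject_erp <- function(data, time_ms, sampling_rate_hz,
                            subject_id, group, condition) {
  step <- diff(time_ms)
  if (length(step) && (any(step <= 0) ||
                       max(abs(step - step[1])) > 1e-9)) {
    stop_erpica("time axis must be strictly increasing with a constant step")
  }
  structure(list(
    data = data, time_ms = time_ms, sampling_rate_hz = sampling_rate_hz,
    subject_id = subject_id, group = group, condition = condition
  ), class = "subject_erp")
}

#' Simulate a two-group ERP dataset
#'
#' Generates `n_per_group` controls and cases, each with an averaged ERP per
#' condition in the ground-truth condition map (NOGO and NOVEL by default).
#' Fully deterministic given `(gt, config)`: per-subject seeds are drawn from
#' `config$seed`.
#'
#' @param gt A [ground_truth()].
#' @param config A [sim_config()].
#' @return An `erp_dataset`: nested list `erps[[subject_id]][[condition]]` of
#'   `subject_erp` objects, a `subjects` data frame (subject_id, group),
#'   conditions, channels, time axis and sampling rate, with the generating
#'   ground truth attached as provenance.
#' @export
simulate_dataset <- function(gt, config) {
  conditions <- names(gt$condition_map)
  n <- config$n_per_group
  ids <- c(sprintf("control_%03d", seq_len(n)), sprintf("case_%03d", seq_len(n)))
  groups <- rep(c("control", "case"), each = n)
  subject_seeds <- local_seed(config$seed,
                              sample.int(.Machine$integer.max - 1L, 2L * n))
  erps <- vector("list", 2L * n)
  names(erps) <- ids
  for (i in seq_along(ids)) {
    per_cond <- lapply(conditions, function(cond) {
      simulate_subject(gt, config, groups[i], subject_seeds[i],
                       condition = cond, subject_id = ids[i])
    })
    names(per_cond) <- conditions
    erps[[i]] <- per_cond
  }
  structure(list(
    erps = erps,
    subjects = data.frame(subject_id = ids, group = groups,
                          stringsAsFactors = FALSE),
    conditions = conditions,
    channels = config$channels,
    time_ms = time_axis_ms(config),
    sampling_rate_hz = config$sampling_rate_hz,
    ground_truth = gt,
    config = config
  ), class = "erp_dataset")
}

#' Simulate raw epochs with planted artifacts
#'
#' Builds an epoch set for exercising the rejection rules: clean epochs with
#' comfortable margins below every threshold, plus epochs violating exactly one
#' rule each — an amplitude spike (150 microvolt peak vs the 100 microvolt
#' rule), a 27.5 Hz oscillation (60 microvolt vs the 35 microvolt in-band
#' rule), and a 0.5 Hz wave (75 microvolt vs the 50 microvolt in-band rule).
#' All margins exceed 10% so a correct classifier must agree with the planted
#' labels exactly.
#'
#' @param config A [sim_config()] (channels, sampling rate and seed are used).
#' @param n_clean,n_amp,n_fast,n_slow Epoch counts per planted category.
#' @param epoch_ms Epoch duration in ms (default 1200).
#' @return An `epoch_set`: list of C x T matrices, sampling rate, planted
#'   category codes, and empty rejection slots filled by [reject_epochs()].
#' @export
simulate_artifact_epochs <- function(config, n_clean, n_amp, n_fast, n_slow,
                                     epoch_ms = 1200) {
  stopifnot(n_clean >= 0, n_amp >= 0, n_fast >= 0, n_slow >= 0)
  C <- length(config$channels)
  fs <- config$sampling_rate_hz
  tms <- seq(0, epoch_ms - 1000 / fs, by = 1000 / fs)
  T_ <- length(tms)
  planted <- rep(c("clean", "amplitude", "fast", "slow"),
                 c(n_clean, n_amp, n_fast, n_slow))
  epochs <- local_seed(config$seed + 7L, lapply(seq_along(planted), function(i) {
    e <- matrix(stats::rnorm(C * T_, 0, 5), C, T_)
    kind <- planted[i]
    if (kind == "amplitude") {
      e[5, ] <- e[5, ] + 150 * exp(-(tms - epoch_ms / 2)^2 / (2 * 30^2))
    } else if (kind == "fast") {
      osc <- 60 * sin(2 * pi * 27.5 * tms / 1000)
      e[3, ] <- e[3, ] + osc; e[9, ] <- e[9, ] + osc
    } else if (kind == "slow") {
      sl <- 75 * sin(2 * pi * 0.5 * tms / 1000)
      e[1, ] <- e[1, ] + sl; e[2, ] <- e[2, ] + sl
    }
    rownames(e) <- config$channels
    e
  }))
  structure(list(
    epochs = epochs, sampling_rate_hz = fs, time_ms = tms,
    planted = planted, rejected = rep(NA, length(planted)),
    reasons = vector("list", length(planted))
  ), class = "epoch_set")
}
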