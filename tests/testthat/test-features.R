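test_that("template validation rejects impossible settings", {
  expect_error(feature_template(100, 50, 10, 4), "start_ms")
  expect_error(feature_template(0, 600, 700, 4), "window_ms")
  expect_error(feature_template(0, 600, 100, 0), "step_ms")
})

test_that("enumeration count matches the closed form for every window size", {
  counts <- function(start, end, w, step) {
    tp <- feature_template(start, end, w, step)
    nrow(enumerate_features(tp, "c1"))
  }
  expect_equal(counts(0, 600, 600, 4), 1)
  expect_equal(counts(0, 600, 100, 4), 126)
  # closed form checked over a parameter sweep against an independent loop
  for (w in c(50, 75, 100, 125, 150)) {
    for (step in c(4, 20)) {
      n_loop <- 0
      t0 <- 0
      while (t0 + w <= 600) {
        n_loop <- n_loop + 1
        t0 <- t0 + step
      }
      expect_equal(counts(0, 600, w, step), n_loop)
      expect_equal(n_loop, floor((600 - w - 0) / step) + 1)
    }
  }
})

test_that("the full reference grid over 7 components enumerates 17,584 features", {
  specs <- enumerate_features(reference_templates(), paste0("c", 1:7))
  expect_equal(nrow(specs), 17584)
  expect_equal(anyDuplicated(specs$id), 0)
})

test_that("extraction returns planted extrema, honors ties and windows", {
  tms <- seq(0, 600, by = 4)
  tc <- -exp(-(tms - 200)^2 / (2 * 20^2))     # unique trough at 200 ms
  spec <- list(t0_ms = 112, t1_ms = 260, extremum = "min", returns = "latency")
  expect_equal(extract_feature(spec, tc, tms), 200)
  spec$returns <- "amplitude"
  expect_equal(extract_feature(spec, tc, tms), -1)
  # constant waveform: earliest-sample tie rule
  spec2 <- list(t0_ms = 100, t1_ms = 200, extremum = "min", returns = "latency")
  expect_equal(extract_feature(spec2, rep(1, length(tms)), tms), 100)
  # sampled Gaussian trough, center 500 sd 30, window 440-540
  g <- -3 * exp(-(tms - 500)^2 / (2 * 30^2))
  spec3 <- list(t0_ms = 440, t1_ms = 540, extremum = "min", returns = "latency")
  expect_equal(extract_feature(spec3, g, tms), 500)
  spec3$returns <- "amplitude"
  expect_equal(extract_feature(spec3, g, tms), -3, tolerance = 1e-6)
  # out-of-span window errors
  spec_bad <- list(t0_ms = 550, t1_ms = 700, extremum = "min", returns = "latency")
  expect_error(extract_feature(spec_bad, tc, tms), "outside")
})

test_that("latency is scale-invariant, amplitude scales linearly, shifts move latency exactly", {
  tms <- seq(0, 600, by = 4)
  tc <- -exp(-(tms - 300)^2 / (2 * 30^2))   # trough at 300 ms, window interior
  spec <- list(t0_ms = 200, t1_ms = 400, extremum = "min", returns = "latency")
  spec_a <- list(t0_ms = 200, t1_ms = 400, extremum = "min", returns = "amplitude")
  lat <- extract_feature(spec, tc, tms)
  expect_equal(extract_feature(spec, 3.7 * tc, tms), lat)
  expect_equal(extract_feature(spec_a, 3.7 * tc, tms),
               3.7 * extract_feature(spec_a, tc, tms))
  # shifting by a whole number of samples shifts latency by exactly that
  for (d in c(8, 20)) {
    shifted <- c(rep(tc[1], d / 4), tc[1:(length(tc) - d / 4)])
    expect_equal(extract_feature(spec, shifted, tms), lat + d)
  }
})

test_that("feature matrix is complete, windows bound latencies, group shift is recovered", {
  shift <- c(0, 0, 0, 24, 0, 0, 0)
  cfg <- tiny_config(seed = 31, n = 5, noise = 0.2, jitter = 2, shift = shift)
  gt <- make_ground_truth(cfg, 7)
  ds <- simulate_dataset(gt, cfg)
  # noise-subspace rotation has no unique optimum; tol may not be met there
  m <- suppressWarnings(fit_infomax(concat_all(ds), seed = 2))
  mt <- erpica:::greedy_match_columns(gt$topographies, m$U_inv)
  comp <- m$component_names[mt$b[mt$a == 4]]   # fitted parietal component
  chan <- m$channel_order[which.max(abs(m$U_inv[, mt$b[mt$a == 4]]))]
  specs <- enumerate_features(
    list(feature_template(440, 580, 120, 20, "min", "latency"),
         feature_template(440, 580, 120, 20, "min", "amplitude")),
    comp, stats::setNames(list(chan), comp))
  fm <- build_feature_matrix(ds, m, specs,
                             stats::setNames(list(chan), comp),
                             stats::setNames(list("NOGO"), comp))
  expect_equal(dim(fm$values), c(10, nrow(specs)))
  expect_false(anyNA(fm$values))
  lat_cols <- which(specs$returns == "latency")
  for (k in lat_cols) {
    expect_true(all(fm$values[, k] >= specs$t0_ms[k] &
                    fm$values[, k] <= specs$t1_ms[k]))
  }
  # group-mean latency difference of the trough feature ~ planted 24 ms
  k <- which(specs$t0_ms == 460 & specs$returns == "latency")[1]
  d <- mean(fm$values[fm$group_labels == "case", k]) -
    mean(fm$values[fm$group_labels == "control", k])
  expect_lt(abs(d - 24), 8)   # within jitter noise + one sample
  # missing condition errors name the subject
  ds_bad <- ds
  ds_bad$erps[[3]][["NOGO"]] <- NULL
  expect_error(build_feature_matrix(ds_bad, m, specs,
                                    stats::setNames(list(chan), comp),
                                    stats::setNames(list("NOGO"), comp)),
               "missing condition")
})
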