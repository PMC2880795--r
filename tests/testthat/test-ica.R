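test_that("Infomax separates a 2-channel Laplacian mixture and agrees with the rotation-search oracle", {
  S <- laplacian_sources(5000, 42)
  A <- matrix(c(1, .6, .4, 1), 2, 2)
  X <- A %*% S
  m <- fit_infomax(X, seed = 3)
  rec <- m$U %*% X
  cc <- abs(cor(t(rec), t(S)))
  expect_gte(max(cc[1, ]), 0.95)
  expect_gte(max(cc[2, ]), 0.95)
  expect_true(all(apply(cc, 2, max) >= 0.95))  # each source recovered by someone
  S_oracle <- oracle_rotation_ica(X)
  cc_o <- abs(cor(t(rec), t(S_oracle)))
  expect_true(all(apply(cc_o, 2, max) >= 0.95))
})

test_that("already-independent rows give a near-signed-permutation unmixing", {
  S <- laplacian_sources(8000, 7)
  m <- fit_infomax(S, seed = 1)
  G <- m$U %*% diag(apply(S, 1, sd))  # gain matrix in source units
  G <- abs(G / apply(G, 1, function(r) max(abs(r))))
  # each row dominated by a single entry
  second_largest <- apply(G, 1, function(r) sort(r, decreasing = TRUE)[2])
  expect_true(all(second_largest < 0.2))
})

test_that("fit is deterministic given the seed", {
  S <- laplacian_sources(3000, 9)
  A <- matrix(c(1, .3, .7, 1), 2, 2)
  m1 <- fit_infomax(A %*% S, seed = 5)
  m2 <- fit_infomax(A %*% S, seed = 5)
  expect_identical(m1$U, m2$U)
})

test_that("projector invariants hold for a fitted 19-channel model", {
  m <- fitted_toy_model()$model
  C <- ncol(m$U)
  expect_lt(max(abs(m$U %*% m$U_inv - diag(C))), 1e-8)
  Fs <- lapply(seq_len(C), function(i) spatial_filter(m, i))
  for (i in c(1, 5, 12)) {
    expect_lt(max(abs(Fs[[i]] %*% Fs[[i]] - Fs[[i]])), 1e-8)  # idempotent
  }
  expect_lt(max(abs(Fs[[1]] %*% Fs[[2]])), 1e-8)              # annihilating
  expect_lt(max(abs(Reduce(`+`, Fs) - diag(C))), 1e-8)        # complete
})

test_that("sum of filters is the identity for a random invertible 3x3 model", {
  U <- withr::with_seed(4, matrix(rnorm(9), 3, 3))
  m <- structure(list(U = U, U_inv = solve(U),
                      channel_order = c("a", "b", "c"),
                      component_names = c("IC1", "IC2", "IC3")),
                 class = "mixing_model")
  Fsum <- spatial_filter(m, 1) + spatial_filter(m, 2) + spatial_filter(m, 3)
  expect_equal(Fsum, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("timecourses and projections obey the decomposition identities", {
  toy <- fitted_toy_model()
  m <- toy$model
  P <- toy$dataset$erps[[2]][["NOGO"]]$data
  C <- nrow(P)
  # P = U_inv S with known S: timecourse returns S rows exactly
  S <- m$U %*% P
  expect_equal(component_timecourse(m, 3, P), unname(S[3, ]), tolerance = 1e-10)
  expect_true(all(component_timecourse(m, 2, P * 0) == 0))
  # completeness and idempotence of projections
  Psum <- Reduce(`+`, lapply(seq_len(C), function(i) project_component(m, i, P)))
  expect_lt(max(abs(Psum - P)), 1e-8)
  P1 <- project_component(m, 1, P)
  expect_equal(project_component(m, 1, P1), P1, tolerance = 1e-8)
  expect_equal(qr(project_component(m, 4, P))$rank, 1)   # rank 1
  # channel mismatch guard
  Pbad <- P[c(2, 1, 3:19), ]
  expect_error(component_timecourse(m, 1, Pbad), "order mismatch")
})

test_that("planted trough latency is recovered from the matched component timecourse", {
  toy <- fitted_toy_model()
  m <- toy$model
  gt <- toy$gt
  ds <- toy$dataset
  mt <- erpica:::greedy_match_columns(gt$topographies, m$U_inv)
  # source 4 (parietal) has an analytic trough at 510 ms
  comp <- mt$b[mt$a == 4]
  grand <- Reduce(`+`, lapply(ds$erps, function(s) s$NOGO$data)) /
    length(ds$erps)
  tc <- component_timecourse(m, comp, grand)
  sign_flip <- sign(cor(m$U_inv[, comp], gt$topographies[, 4]))
  lat <- ds$time_ms[which.min(sign_flip * tc)]
  expect_lte(abs(lat - 510), 16)  # subject jitter (sd 8 ms) shifts the mean a bit
})

test_that("explained power fraction is 0 for none, 1 for all, ~1 for all true sources", {
  toy <- fitted_toy_model()
  m <- toy$model
  P <- concat_all(toy$dataset)
  expect_equal(explained_power_fraction(m, integer(0), P), 0)
  expect_equal(explained_power_fraction(m, seq_len(ncol(m$U)), P),
               1, tolerance = 1e-8)
  mt <- erpica:::greedy_match_columns(toy$gt$topographies, m$U_inv)
  expect_gte(explained_power_fraction(m, sort(mt$b), P), 0.99)
  expect_error(explained_power_fraction(m, 1, P * 0), "zero-power")
})

test_that("topographies are reproducible across seeds after convention normalization", {
  toy <- fitted_toy_model()
  P <- concat_all(toy$dataset)
  m1 <- toy$model
  m2 <- fit_infomax(P, seed = 77)
  k <- m1$signal_rank
  expect_lt(max(abs(m1$U_inv[, 1:k] - m2$U_inv[, 1:k])), 1e-3)
})

test_that("split-half stability: identical halves are perfectly stable, permutation-invariant", {
  cfg <- tiny_config(seed = 13, n = 4, noise = 0.3, jitter = 6)
  gt <- make_ground_truth(cfg, 7)
  ds <- simulate_dataset(gt, cfg)
  # duplicate one subject's data into every slot: any split yields two
  # identical halves, so every matched |correlation| must be 1
  dup <- ds
  for (id in ds$subjects$subject_id) dup$erps[[id]] <- ds$erps[[1]]
  rep1 <- suppressWarnings(split_half_stability(dup, n_components = 7, seed = 2))
  expect_equal(rep1$mean_abs_correlation, 1, tolerance = 1e-6)
  # permuting subject order does not change the report
  perm <- ds
  ord <- rev(seq_len(nrow(ds$subjects)))
  perm$subjects <- ds$subjects[ord, ]
  perm$erps <- ds$erps[ord]
  ra <- suppressWarnings(split_half_stability(ds, n_components = 7, seed = 5))
  rb <- suppressWarnings(split_half_stability(perm, n_components = 7, seed = 5))
  expect_equal(ra$matched_pairs, rb$matched_pairs)
  expect_error(split_half_stability(structure(list(
    subjects = data.frame(subject_id = c("a", "b"), group = c("x", "y"))),
    class = "erp_dataset")), "at least 4")
})
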