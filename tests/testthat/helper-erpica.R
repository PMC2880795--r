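# Shared fixtures: small deterministic configs and datasets built in code.

tiny_config <- function(seed = 11L, n = 4, noise = 0, jitter = 0,
                        amp_jitter = 0, shift = 0) {
  sim_config(n_per_group = n, seed = seed, noise_sd_uv = noise,
             subject_latency_jitter_sd_ms = jitter,
             subject_amplitude_jitter_sdlog = amp_jitter,
             group_latency_shift_ms = shift)
}

# Concatenate every subject x condition ERP of a dataset into one C x T matrix.
concat_all <- function(dataset) {
  do.call(cbind, unlist(lapply(dataset$erps, function(s) {
    lapply(s, function(e) e$data)
  }), recursive = FALSE))
}

# A small fitted model on well-separated synthetic data, reused across tests.
fitted_toy_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_config(seed = 3, n = 6, noise = 0, jitter = 8)
      gt <- make_ground_truth(cfg, 7)
      ds <- simulate_dataset(gt, cfg)
      cache <<- list(model = fit_infomax(concat_all(ds), seed = 2),
                     gt = gt, dataset = ds, config = cfg)
    }
    cache
  }
})

# Independent oracle for the 2-channel case: whiten, then brute-force search
# over rotation angles for the rotation maximizing total |excess kurtosis| of
# the unmixed sources. Shares no code with fit_infomax.
oracle_rotation_ica <- function(X, n_grid = 720) {
  Xc <- X - rowMeans(X)
  eg <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE)
  Wh <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  Z <- Wh %*% Xc
  kurt <- function(v) mean(v^4) / mean(v^2)^2 - 3
  best <- -Inf
  best_S <- NULL
  for (theta in seq(0, pi / 2, length.out = n_grid)) {
    R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    S <- R %*% Z
    score <- abs(kurt(S[1, ])) + abs(kurt(S[2, ]))
    if (score > best) {
      best <- score
      best_S <- S
    }
  }
  best_S
}

laplacian_sources <- function(Tn, seed) {
  withr::with_seed(seed, rbind(sign(runif(Tn) - .5) * rexp(Tn),
                               sign(runif(Tn) - .5) * rexp(Tn)))
}

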