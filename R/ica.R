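# Infomax ICA on group-level ERP matrices and the projector algebra of
# per-component spatial filters.
#
# Model: S = U P with square unmixing U (channels x channels); the i-th
# spatial filter F_i = U^-1 U_zi (U with all rows but i zeroed) is an oblique
# projector extracting component i's scalp contribution: F_i F_i = F_i,
# F_i F_j = 0 for i != j, and sum_i F_i = I.

#' Fit Infomax ICA to a channels-by-time ERP matrix
#'
#' Bell-Sejnowski Infomax with the logistic nonlinearity and the natural
#' gradient: rows are mean-centered, the data are whitened by PCA, and an
#' unmixing rotation is learned by gradient ascent on the joint entropy of the
#' logistic-transformed outputs. The learning rate anneals (x `anneal`) when
#' the gradient direction turns by more than 60 degrees between iterations;
#' iteration stops when the relative weight change drops below `tol`. The
#' default rate 0.05 reliably converges within a few hundred iterations on
#' whitened data; much smaller rates cannot reach `tol` inside `max_iter`.
#'
#' Average-referenced input is rank deficient by construction (channel means
#' are zero), so the rotation is estimated in the subspace of eigenvalues
#' greater than `rank_tol` times the largest; the square model is completed
#' with the orthonormal null-space basis, whose components carry (numerically)
#' zero power and sort last. Components are ordered by descending explained
#' power and signs are fixed so each topography's largest-magnitude entry is
#' positive; with those conventions the decomposition is reproducible across
#' seeds on well-separated data.
#'
#' @param P C x T numeric matrix (channels x concatenated time samples),
#'   typically the horizontal concatenation of subject ERPs.
#' @param max_iter Maximum iterations (default 1024).
#' @param tol Stop when `||dW||_F / ||W||_F` falls below this (default 1e-7).
#' @param lr Initial learning rate (default 0.05).
#' @param seed Seed for the random orthonormal initialization.
#' @param rank_tol Relative eigenvalue cutoff for the retained subspace.
#' @param anneal Learning-rate multiplier applied on >60 degree gradient turns.
#' @param channel_order Optional channel names; defaults to rownames of `P`.
#' @return A `mixing_model`: square unmixing `U` (K x C), mixing `U_inv`
#'   (columns are component topographies), `channel_order`, `component_names`,
#'   per-component `explained_power` fractions (descending), `signal_rank`,
#'   `iterations`, `converged`, and `seed`.
#' @export
fit_infomax <- function(P, max_iter = 1024, tol = 1e-7, lr = 0.05,
                        seed = 1L, rank_tol = 1e-9, anneal = 0.9,
                        channel_order = rownames(P)) {
  P <- as.matrix(P)
  C <- nrow(P)
  T_ <- ncol(P)
  if (T_ <= C) stop_erpica("need more time samples than channels")
  if (is.null(channel_order)) channel_order <- paste0("ch", seq_len(C))
  mu <- rowMeans(P)
  Xc <- P - mu
  cv <- tcrossprod(Xc) / T_
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  r <- sum(ev > rank_tol * max(ev))
  if (r < 2) stop_erpica("input has fewer than 2 non-degenerate dimensions; ",
                         "reduce dimensionality or check the data")
  E_r <- eg$vectors[, seq_len(r), drop = FALSE]
  d_r <- ev[seq_len(r)]
  Xw <- sweep(crossprod(E_r, Xc), 1, sqrt(d_r), "/")   # r x T, white

  # natural-gradient Infomax on the whitened data
  W <- local_seed(seed, qr.Q(qr(matrix(stats::rnorm(r * r), r, r))))
  G_prev <- NULL
  converged <- FALSE
  iter <- 0L
  rate <- lr
  I_r <- diag(r)
  while (iter < max_iter) {
    iter <- iter + 1L
    U_s <- W %*% Xw
    Y <- 1 / (1 + exp(-U_s))
    G <- (I_r + ((1 - 2 * Y) %*% t(U_s)) / T_)          # natural gradient factor
    dW <- rate * G %*% W
    if (!is.null(G_prev)) {
      num <- sum(G * G_prev)
      den <- sqrt(sum(G^2) * sum(G_prev^2))
      if (den > 0 && num / den < cos(60 * pi / 180)) rate <- rate * anneal
    }
    G_prev <- G
    W <- W + dW
    if (sqrt(sum(dW^2)) / sqrt(sum(W^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("Infomax did not reach tol within ", max_iter, " iterations")
  }

  # back to channel space; complete the basis with the null complement
  A_r <- E_r %*% (sqrt(d_r) * solve(W))                 # C x r mixing
  if (r < C) {
    E_null <- eg$vectors[, (r + 1):C, drop = FALSE]
    U_inv <- cbind(A_r, E_null)
  } else {
    U_inv <- A_r
  }
  U <- solve(U_inv)

  # order by descending explained power of F_i P, fix topography signs
  src <- U %*% Xc
  pow <- colSums(U_inv^2) * rowSums(src^2)              # ||a_i||^2 ||s_i||^2
  ord <- order(pow, decreasing = TRUE)
  U <- U[ord, , drop = FALSE]
  U_inv <- U_inv[, ord, drop = FALSE]
  pow <- pow[ord]
  for (i in seq_len(C)) {
    j <- which.max(abs(U_inv[, i]))
    if (U_inv[j, i] < 0) {
      U_inv[, i] <- -U_inv[, i]
      U[i, ] <- -U[i, ]
    }
  }
  rownames(U_inv) <- channel_order
  colnames(U) <- channel_order
  names <- paste0("IC", seq_len(C))
  colnames(U_inv) <- names
  rownames(U) <- names
  structure(list(
    U = U, U_inv = U_inv, channel_order = channel_order,
    component_names = names,
    explained_power = pow / sum(pow),
    signal_rank = r, iterations = iter, converged = converged,
    seed = as.integer(seed), sign_convention = "max-abs topography entry positive"
  ), class = "mixing_model")
}

check_channels <- function(model, P) {
  if (nrow(P) != length(model$channel_order)) {
    stop_erpica("channel count mismatch between model and data")
  }
  rn <- rownames(P)
  if (!is.null(rn) && !identical(rn, model$channel_order)) {
    stop_erpica("channel order mismatch between model and data")
  }
  invisible(TRUE)
}

#' Spatial filter of one component
#'
#' `F_i = U^-1 U_zi`, the rank-1 oblique projector (topography times unmixing
#' row) that extracts component i's contribution from channel space.
#'
#' @param model A `mixing_model`.
#' @param i Component index.
#' @return C x C matrix.
#' @export
spatial_filter <- function(model, i) {
  if (length(i) != 1 || i < 1 || i > ncol(model$U_inv)) {
    stop_erpica("invalid component index")
  }
  outer(model$U_inv[, i], model$U[i, ])
}

#' Component activation time course
#'
#' Row i of `U %*% P`.
#'
#' @param model A `mixing_model`.
#' @param i Component index.
#' @param P C x T matrix in the model's channel order.
#' @return Numeric vector of length T.
#' @export
component_timecourse <- function(model, i, P) {
  check_channels(model, P)
  if (length(i) != 1 || i < 1 || i > nrow(model$U)) {
    stop_erpica("invalid component index")
  }
  drop(model$U[i, , drop = FALSE] %*% P)
}

#' Scalp projection of one component
#'
#' `P_i = F_i %*% P`; the projections of all components sum back to `P`.
#'
#' @inheritParams component_timecourse
#' @return C x T matrix (rank 1).
#' @export
project_component <- function(model, i, P) {
  check_channels(model, P)
  spatial_filter(model, i) %*% P
}

#' Fraction of signal power explained by a component subset
#'
#' Sum of squares of the summed projections of the chosen components divided
#' by the sum of squares of `P`.
#'
#' @param model A `mixing_model`.
#' @param indices Component indices (possibly empty).
#' @param P C x T matrix.
#' @return Scalar in `[0, 1]` (can marginally exceed 1 for oblique overlaps).
#' @export
explained_power_fraction <- function(model, indices, P) {
  check_channels(model, P)
  tot <- sum(P^2)
  if (tot == 0) stop_erpica("zero-power input")
  if (length(indices) == 0) return(0)
  R <- Reduce(`+`, lapply(indices, function(i) project_component(model, i, P)))
  sum(R^2) / tot
}

#' Split-half stability of the decomposition
#'
#' Randomly halves the subjects, computes each half's grand-average ERP
#' (conditions concatenated), fits ICA independently per half, and greedily
#' matches components across halves by maximum absolute topography
#' correlation. With `n_components` set, only the top components by explained
#' power enter the report — the stability question concerns the retained
#' components, not the near-zero-power remainder of a square model.
#'
#' @param dataset An `erp_dataset`.
#' @param n_components Number of top components compared per half (default all).
#' @param seed Seed for the random split.
#' @param ica_seed,max_iter,tol,lr Passed to [fit_infomax()].
#' @return A `stability_report`: `matched_pairs` data frame (component in half
#'   A, in half B, absolute topography correlation), `mean_abs_correlation`,
#'   `split_seed`.
#' @export
split_half_stability <- function(dataset, n_components = NULL, seed = 1L,
                                 ica_seed = 1L, max_iter = 1024, tol = 1e-7,
                                 lr = 0.05) {
  ids <- sort(dataset$subjects$subject_id)
  n <- length(ids)
  if (n < 4) stop_erpica("need at least 4 subjects for a split-half analysis")
  half_a <- local_seed(seed, sort(sample(ids, floor(n / 2))))
  half_b <- setdiff(ids, half_a)
  grand <- function(sub_ids) {
    mats <- lapply(dataset$conditions, function(cond) {
      Reduce(`+`, lapply(sub_ids, function(id) dataset$erps[[id]][[cond]]$data)) /
        length(sub_ids)
    })
    do.call(cbind, mats)
  }
  fit <- function(sub_ids) {
    fit_infomax(grand(sub_ids), max_iter = max_iter, tol = tol, lr = lr,
                seed = ica_seed, channel_order = dataset$channels)
  }
  ma <- fit(half_a)
  mb <- fit(half_b)
  k <- n_components %||% length(ma$component_names)
  k <- min(k, ncol(ma$U_inv), ncol(mb$U_inv))
  pairs <- greedy_match_columns(ma$U_inv[, seq_len(k), drop = FALSE],
                                mb$U_inv[, seq_len(k), drop = FALSE])
  names(pairs) <- c("component_a", "component_b", "abs_correlation")
  structure(list(
    matched_pairs = pairs,
    mean_abs_correlation = mean(pairs$abs_correlation),
    split_seed = as.integer(seed),
    half_a = half_a, half_b = half_b
  ), class = "stability_report")
}
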