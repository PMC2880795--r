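# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Greedy bijective matching of columns of A to columns of B by |correlation|.
# Returns a data.frame with one row per matched pair, strongest match first.
greedy_match_columns <- function(A, B) {
  cmat <- abs(stats::cor(A, B))
  k <- min(ncol(A), ncol(B))
  out <- data.frame(a = integer(k), b = integer(k), abs_correlation = numeric(k))
  for (m in seq_len(k)) {
    idx <- arrayInd(which.max(cmat), dim(cmat))
    out$a[m] <- idx[1]
    out$b[m] <- idx[2]
    out$abs_correlation[m] <- cmat[idx[1], idx[2]]
    cmat[idx[1], ] <- -Inf
    cmat[, idx[2]] <- -Inf
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_erpica <- function(...) stop(..., call. = FALSE)
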