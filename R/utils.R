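# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg, ...) {
  if (isTRUE(cond)) rlang::abort(sprintf(msg, ...))
  invisible(NULL)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds from one parent seed, all < 2^31.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Half-open bin lookup: index i such that edges[i] <= x < edges[i + 1].
find_bin <- function(x, edges) {
  idx <- findInterval(x, edges, left.open = FALSE, rightmost.closed = FALSE)
  idx[x >= edges[length(edges)]] <- NA_integer_
  idx[idx == 0L] <- NA_integer_
  idx
}

# Centered class-indicator (dummy) matrix, one column per group level.
dummy_matrix <- function(groups) {
  groups <- as.factor(groups)
  lv <- levels(groups)
  abort_if(length(lv) < 2L, "need at least 2 groups, got %d", length(lv))
  y <- vapply(lv, function(g) as.numeric(groups == g), numeric(length(groups)))
  colnames(y) <- lv
  y
}

center_cols <- function(x) {
  mu <- colMeans(x)
  list(x = sweep(x, 2L, mu, "-"), means = mu)
}

# Deterministic sign convention: flip v so its largest-|.| entry is positive.
sign_fix <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -1 else 1
}
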