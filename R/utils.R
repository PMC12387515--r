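#' Largest-remainder apportionment
#'
#' Allocate an integer total `n` across groups proportionally to `weights`,
#' assigning floors first and distributing the remaining units to the groups
#' with the largest fractional parts. Ties in fractional part are broken by
#' group order, so the allocation is fully deterministic.
#'
#' @param n Integer total to allocate (`n >= 0`).
#' @param weights Non-negative weights; they are normalised internally.
#' @return Integer vector of the same length as `weights`, summing to `n`.
#' @examples
#' largest_remainder(127, c(49, 32, 46) / 127)  # 49 32 46
#' largest_remainder(125, rep(1, 3))            # 42 42 41
#' @export
largest_remainder <- function(n, weights) {
  stopifnot(length(n) == 1L, n >= 0, n == round(n))
  if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative, finite, and not all zero")
  }
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    # order(): ties broken by position, i.e. by group order
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

# Deterministic 31-bit seed derived from a master seed and a stream name /
# indices. A small multiplicative fold; products stay < 2^53 so doubles are
# exact. Not cryptographic -- just stable, collision-sparse stream separation.
#' Derive a substream seed
#'
#' Maps a master seed plus a stream label (and optional integer indices) to a
#' reproducible seed in `[0, 2^31 - 2]`, so that each pipeline stage or Monte
#' Carlo cell can be seeded independently of the others.
#'
#' @param master Master integer seed.
#' @param name Character stream label, e.g. `"cohort"` or `"tsne"`.
#' @param ... Optional extra integer indices (e.g. grid cell coordinates).
#' @return A single integer seed.
#' @export
substream_seed <- function(master, name, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- (abs(as.numeric(master)) %% m)
  mix <- function(h, x) ((h * 69069) %% m + (as.numeric(x) %% m)) %% m
  for (ch in utf8ToInt(as.character(name))) h <- mix(h, ch)
  for (idx in list(...)) {
    for (v in idx) h <- mix(h, round(as.numeric(v) * 1000))
  }
  as.integer(h)
}

# run expr with a local RNG state (restores caller's .Random.seed)
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
  })
  set.seed(seed)
  force(expr)
}

# scalar integer check for argument validation
assert_count <- function(x, name, min = 1) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  invisible(as.integer(x))
}

assert_cols <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
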