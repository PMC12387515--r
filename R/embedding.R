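#' t-SNE embedding configuration
#'
#' Defaults mirror the analysis this package implements: the clustering
#' inputs are age, BMI and fatigue severity; two output dimensions;
#' perplexity 20; at most 500 gradient-descent iterations; deterministic
#' initialization from the first two principal components.
#'
#' @param features Ordered feature names used for the embedding.
#' @param out_dims Output dimensionality (2 unless explicitly overridden).
#' @param perplexity Effective number of nearest neighbours (> 0).
#' @param max_iter Gradient-descent iterations (>= 1).
#' @param pca_init Initialise from the first `out_dims` principal
#'   components, scaled to sd 1e-4 (removes run-to-run sign flips); when
#'   `FALSE` a small random Gaussian initialization seeded by `seed` is
#'   used.
#' @param auto_perplexity When `n < 3 * perplexity + 2`, shrink perplexity
#'   to `floor((n - 1) / 3)` with a warning instead of failing.
#' @param seed Integer seed (only consumed when `pca_init = FALSE`, but
#'   always echoed into the result for provenance).
#' @param learning_rate,exaggeration Optimizer settings; the early
#'   exaggeration factor is applied for the first quarter of the
#'   iterations, and momentum switches 0.5 -> 0.8 at the same point.
#' @return An object of class `embed_config`.
#' @export
embed_config <- function(features = c("age", "bmi", "fss_score"),
                         out_dims = 2, perplexity = 20, max_iter = 500,
                         pca_init = TRUE, auto_perplexity = FALSE,
                         seed = 1L, learning_rate = 200, exaggeration = 12) {
  if (perplexity <= 0) stop("perplexity must be > 0")
  assert_count(max_iter, "max_iter")
  assert_count(out_dims, "out_dims")
  structure(
    list(
      features = features, out_dims = as.integer(out_dims),
      perplexity = perplexity, max_iter = as.integer(max_iter),
      pca_init = isTRUE(pca_init), auto_perplexity = isTRUE(auto_perplexity),
      seed = as.integer(seed), learning_rate = learning_rate,
      exaggeration = exaggeration
    ),
    class = "embed_config"
  )
}

#' Z-score the clustering features of a cohort
#'
#' Each requested column is centred and scaled to unit variance (sample SD,
#' denominator n - 1), so that variables on very different measurement
#' scales (years of age vs. a 1-7 fatigue score) contribute comparably to
#' the embedding distances.
#'
#' @param cohort Cohort data frame.
#' @param features Column names to standardize.
#' @return A numeric matrix with attributes `center` and `scale` (the
#'   per-feature means and SDs) and rownames from the cohort `id` column
#'   when present.
#' @export
standardize_features <- function(cohort, features = c("age", "bmi", "fss_score")) {
  assert_cols(cohort, features)
  x <- as.matrix(cohort[features])
  if (!is.numeric(x)) stop("features must all be numeric")
  bad_row <- which(!stats::complete.cases(x) | apply(!is.finite(x), 1, any))
  if (length(bad_row)) {
    stop(sprintf("non-finite value in row %d", bad_row[1L]))
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop(
      "constant feature cannot be standardized: ",
      features[which(sds == 0)[1L]]
    )
  }
  out <- scale(x)
  rownames(out) <- if ("id" %in% names(cohort)) cohort$id else NULL
  attr(out, "center") <- stats::setNames(attr(out, "scaled:center"), features)
  attr(out, "scale") <- stats::setNames(attr(out, "scaled:scale"), features)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Embed a feature matrix with exact t-SNE
#'
#' Runs exact (dense) t-SNE: Gaussian input affinities calibrated per point
#' to the target perplexity, Student-t output kernel, gradient descent with
#' early exaggeration, momentum and adaptive gains. With PCA
#' initialization (the default) the embedding is fully deterministic for a
#' given input matrix and configuration.
#'
#' @param x Numeric matrix (rows = participants), typically the output of
#'   [standardize_features()].
#' @param config An [embed_config()].
#' @return An object of class `embedding_result`: list with `coords` (n x
#'   out_dims matrix, rownames preserved), `config` (including the
#'   effective perplexity actually used), `seed`, and `scaling` (the
#'   standardization parameters carried over from `x`, if any).
#' @export
tsne_embed <- function(x, config = embed_config()) {
  stopifnot(inherits(config, "embed_config"))
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("input matrix contains non-finite values")
  n <- nrow(x)
  perplexity <- config$perplexity
  if (n < 3 * perplexity + 2) {
    if (config$auto_perplexity) {
      perplexity <- floor((n - 1) / 3)
      warning(sprintf(
        "perplexity shrunk to %d to satisfy n >= 3 * perplexity + 2 (n = %d)",
        perplexity, n
      ))
      if (perplexity < 1) stop("too few rows to embed")
    } else {
      stop(sprintf(
        "n = %d is too small for perplexity %g (need n >= 3 * perplexity + 2); set auto_perplexity = TRUE to shrink it",
        n, perplexity
      ))
    }
  }
  # canonical row order: floating-point summation order then matches for
  # any permutation of the same rows, making the embedding exactly
  # permutation-equivariant (t-SNE gradient descent would otherwise
  # amplify last-bit differences)
  ord <- do.call(order, split(x, col(x)))
  xs <- x[ord, , drop = FALSE]
  p <- tsne_affinities(xs, perplexity)
  y0 <- if (config$pca_init) {
    pc <- stats::prcomp(xs, center = TRUE, scale. = FALSE)
    init <- pc$x[, seq_len(config$out_dims), drop = FALSE]
    init / stats::sd(init[, 1]) * 1e-4
  } else {
    with_seed(
      config$seed,
      matrix(stats::rnorm(n * config$out_dims, sd = 1e-4), n)
    )
  }
  quarter <- max(1L, config$max_iter %/% 4L)
  coords <- tsne_optimize(
    p, y0,
    max_iter = config$max_iter,
    learning_rate = config$learning_rate,
    exaggeration = config$exaggeration,
    exaggeration_iter = quarter, momentum_switch_iter = quarter
  )
  coords <- coords[order(ord), , drop = FALSE] # back to input order
  colnames(coords) <- paste0("tsne", seq_len(config$out_dims))
  rownames(coords) <- rownames(x)
  cfg <- config
  cfg$perplexity_effective <- perplexity
  structure(
    list(
      coords = coords, config = cfg, seed = config$seed,
      scaling = list(
        center = attr(x, "center"), scale = attr(x, "scale")
      )
    ),
    class = "embedding_result"
  )
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf(
    "t-SNE embedding: %d points in %d dimensions (perplexity %g, %d iterations, %s initialization)\n",
    nrow(x$coords), ncol(x$coords), x$config$perplexity_effective,
    x$config$max_iter, if (x$config$pca_init) "PCA" else "random"
  ))
  invisible(x)
}
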