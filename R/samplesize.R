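#' Monte Carlo sample-size simulation configuration
#'
#' Grid definition for the silhouette-vs-sample-size simulation: candidate
#' sample sizes 50..250 in steps of 25, cluster counts k = 2..10, 1000
#' iterations per cell, moderately separated spherical Gaussian clusters
#' (every pairwise centre distance equal to Cohen's d = 1 in pooled-SD
#' units) in a 3-dimensional feature space.
#'
#' @param n_grid Integer sample sizes to simulate.
#' @param k_grid Integer cluster counts to simulate.
#' @param reps Monte Carlo iterations per (n, k) cell.
#' @param effect_d Pairwise centre separation in pooled-SD units.
#' @param n_features Dimensionality of the simulated feature space.
#' @param seed Master seed; each (n, k, rep) gets its own substream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_grid = seq(50, 250, by = 25), k_grid = 2:10,
                       reps = 1000, effect_d = 1, n_features = 3,
                       seed = 1L) {
  assert_count(reps, "reps")
  assert_count(n_features, "n_features")
  if (effect_d < 0) stop("effect_d must be >= 0")
  if (any(n_grid < 2 * max(k_grid))) {
    stop("every n must be at least twice the largest k")
  }
  structure(
    list(
      n_grid = as.integer(sort(n_grid)), k_grid = as.integer(sort(k_grid)),
      reps = as.integer(reps), effect_d = effect_d,
      n_features = as.integer(n_features), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# k centres with every pairwise distance d: regular simplex in k-1
# dimensions, zero-padded (or truncated, with a warning) to n_features
simplex_centers <- function(k, d, n_features) {
  if (k == 1L) {
    return(matrix(0, 1, n_features))
  }
  e <- diag(k) # pairwise distance sqrt(2)
  e <- sweep(e, 2, colMeans(e)) # centre -> rank k-1
  sv <- svd(e, nu = k - 1)
  centers <- sv$u[, seq_len(k - 1), drop = FALSE] %*%
    diag(sv$d[seq_len(k - 1)], k - 1) * d / sqrt(2)
  if (k - 1 > n_features) {
    warning(sprintf(
      "k - 1 = %d exceeds n_features = %d: the regular simplex is truncated and centre separation is only achieved in the configured subspace",
      k - 1, n_features
    ))
    centers <- centers[, seq_len(n_features), drop = FALSE]
  } else if (k - 1 < n_features) {
    centers <- cbind(centers, matrix(0, k, n_features - (k - 1)))
  }
  centers
}

#' Simulate one clustered Gaussian data set
#'
#' `k` equal-weight (largest-remainder) spherical unit-variance Gaussian
#' clusters whose centres sit at the vertices of a regular simplex scaled so
#' that every pairwise centre distance equals `d`.
#'
#' @param n Sample size (`n >= 2k`).
#' @param k Number of clusters.
#' @param d Pairwise centre separation (Cohen's d).
#' @param n_features Feature-space dimensionality.
#' @param seed Optional integer seed.
#' @return A list with `x` (n x n_features matrix) and `labels`.
#' @export
simulate_clusters <- function(n, k, d, n_features = 3, seed = NULL) {
  assert_count(n, "n", min = 2)
  assert_count(k, "k", min = 1)
  if (n < 2 * k) stop("need n >= 2k")
  centers <- simplex_centers(k, d, n_features)
  sizes <- largest_remainder(n, rep(1, k))
  labels <- rep(seq_len(k), sizes)
  draw <- function() {
    matrix(stats::rnorm(n * n_features), n, n_features) +
      centers[labels, , drop = FALSE]
  }
  x <- if (is.null(seed)) draw() else with_seed(seed, draw())
  list(x = x, labels = labels)
}

# one Monte Carlo rep: simulate, Ward-cluster into k, mean silhouette in
# the same space that was clustered. The simulated features are already on
# a standardized scale (unit pooled within-cluster SD -- that is the unit
# in which d is expressed), so no further rescaling is applied: dividing by
# the total SD would shrink the signal dimensions relative to pure-noise
# dimensions and change the realized effect size.
sim_rep_silhouette <- function(n, k, d, n_features, seed) {
  sim <- simulate_clusters(n, k, d, n_features, seed = seed)
  x <- sim$x
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  if (length(unique(cl)) < 2L) {
    return(0) # degenerate draw
  }
  mean(cluster::silhouette(cl, stats::dist(x))[, "sil_width"])
}

#' Silhouette summary for one grid cell
#'
#' Runs `reps` independent simulate/Ward/silhouette iterations for a single
#' (n, k) combination; the silhouette is computed in the simulated feature
#' space, which is already expressed in pooled within-cluster SD units.
#' Each rep is seeded from its own substream of the master seed, so any
#' cell is reproducible in isolation.
#'
#' @param n,k Cell coordinates.
#' @param d Centre separation.
#' @param n_features Feature-space dimensionality.
#' @param reps Iterations.
#' @param seed Master seed.
#' @return One-row data frame: `n, k, mean, sd, sem, q05, q50, q95, reps`.
#' @export
evaluate_cell <- function(n, k, d = 1, n_features = 3, reps = 100,
                          seed = 1L) {
  assert_count(reps, "reps")
  sils <- vapply(seq_len(reps), function(r) {
    sim_rep_silhouette(n, k, d, n_features,
      seed = substream_seed(seed, "cell", n, k, r)
    )
  }, numeric(1))
  q <- stats::quantile(sils, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  data.frame(
    n = as.integer(n), k = as.integer(k), mean = mean(sils),
    sd = stats::sd(sils), sem = stats::sd(sils) / sqrt(reps),
    q05 = q[1], q50 = q[2], q95 = q[3], reps = as.integer(reps)
  )
}

#' Run the full silhouette-vs-sample-size grid
#'
#' @param config A [sim_config()].
#' @return A data frame of class `samplesize_grid`, one row per (n, k) cell
#'   with the [evaluate_cell()] summaries.
#' @export
run_grid <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cells <- expand.grid(n = config$n_grid, k = config$k_grid)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    evaluate_cell(cells$n[i], cells$k[i],
      d = config$effect_d,
      n_features = config$n_features, reps = config$reps,
      seed = config$seed
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("samplesize_grid", "data.frame")
  attr(out, "config") <- config
  out
}

#' Recommend a sample size at the silhouette plateau
#'
#' For each cluster count k up to `k_max_of_interest`, smooths the mean
#' silhouette as a function of n by isotonic regression (silhouette cannot
#' degrade with more data under the simulation model; the smoothing absorbs
#' Monte Carlo noise) and finds the smallest n whose smoothed silhouette is
#' within `plateau_tol` of the curve's maximum. The recommendation is the
#' largest such n over the considered k (conservative: adequate for every
#' k of interest).
#'
#' @param grid A [run_grid()] result.
#' @param k_max_of_interest Largest k the study design cares about
#'   (default 4: solutions beyond that are rarely interpretable at these
#'   cohort sizes).
#' @param plateau_tol Silhouette units still considered "at the plateau"
#'   (default 0.01).
#' @return A list with `recommended_n`, `per_k` (data frame `k,
#'   plateau_n, max_smoothed`), and `rationale`.
#' @export
recommend_sample_size <- function(grid, k_max_of_interest = 4,
                                  plateau_tol = 0.01) {
  stopifnot(is.data.frame(grid), plateau_tol > 0)
  ks <- sort(unique(grid$k))
  ks <- ks[ks <= k_max_of_interest]
  if (!length(ks)) stop("no grid rows with k <= k_max_of_interest")
  per_k <- do.call(rbind, lapply(ks, function(k) {
    sub <- grid[grid$k == k, ]
    sub <- sub[order(sub$n), ]
    smoothed <- stats::isoreg(sub$n, sub$mean)$yf
    target <- max(smoothed) - plateau_tol
    data.frame(
      k = k, plateau_n = sub$n[which(smoothed >= target)[1L]],
      max_smoothed = max(smoothed)
    )
  }))
  rec <- max(per_k$plateau_n)
  list(
    recommended_n = rec, per_k = per_k,
    rationale = sprintf(
      "smallest n within %.3g silhouette units of the isotonic-smoothed plateau for every k <= %d; conservative maximum over k is n = %d",
      plateau_tol, max(ks), rec
    )
  )
}
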