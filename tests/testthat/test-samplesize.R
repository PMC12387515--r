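test_that("simulated clusters have largest-remainder sizes and simplex geometry", {
  sim <- simulate_clusters(125, 3, d = 1, seed = 1)
  expect_identical(as.integer(table(sim$labels)), c(42L, 42L, 41L))
  expect_equal(dim(sim$x), c(125, 3))

  # every pairwise centre distance equals d when the simplex fits
  sim <- simulate_clusters(8000, 4, d = 2.5, n_features = 5, seed = 2)
  centers <- t(sapply(1:4, function(k) colMeans(sim$x[sim$labels == k, ])))
  pw <- as.vector(dist(centers))
  expect_equal(pw, rep(2.5, 6), tolerance = 0.05) # n = 2000 per cluster

  # k = 2, d = 1, one feature: two unit-variance Gaussians one SD apart
  sim <- simulate_clusters(2000, 2, d = 1, n_features = 1, seed = 3)
  mu <- tapply(sim$x[, 1], sim$labels, mean)
  expect_equal(unname(abs(diff(mu))), 1, tolerance = 0.1)
  expect_equal(sd(sim$x[sim$labels == 1, 1]), 1, tolerance = 0.1)

  expect_error(simulate_clusters(5, 3), "n >= 2k")
  expect_warning(simulate_clusters(50, 5, d = 1, n_features = 2, seed = 1),
    "truncated")
})

test_that("true labels of an unseparated simulation have near-zero silhouette", {
  sim <- simulate_clusters(1000, 3, d = 0, seed = 4)
  s <- silhouette_scores(sim$x, sim$labels)
  expect_lt(abs(s$mean), 0.05)
})

test_that("cell evaluation is deterministic, ordered in d, and well-formed", {
  cell <- evaluate_cell(125, 3, d = 8, reps = 20, seed = 11)
  expect_gt(cell$mean, 0.6) # well-separated blobs
  expect_identical(cell, evaluate_cell(125, 3, d = 8, reps = 20, seed = 11))
  expect_true(cell$q05 <= cell$q50 && cell$q50 <= cell$q95)
  expect_true(all(abs(c(cell$mean, cell$q05, cell$q95)) <= 1))

  means <- sapply(c(0, 3, 8), function(d) {
    evaluate_cell(125, 3, d = d, reps = 30, seed = 12)$mean
  })
  expect_true(all(diff(means) > 0))
})

test_that("the grid covers every (n, k) cell and composes from single cells", {
  cfg <- sim_config(
    n_grid = c(50, 75), k_grid = 2:3, reps = 3, effect_d = 1, seed = 5
  )
  grid <- run_grid(cfg)
  expect_equal(nrow(grid), 4)
  expect_identical(
    nrow(unique(as.data.frame(grid)[c("n", "k")])), 4L
  )
  # a one-cell grid equals the standalone cell evaluation
  one <- run_grid(sim_config(
    n_grid = 75, k_grid = 3, reps = 3, effect_d = 1, seed = 5
  ))
  cell <- evaluate_cell(75, 3, d = 1, reps = 3, seed = 5)
  expect_equal(as.data.frame(one), cell, ignore_attr = TRUE)

  # reps = 1: summaries collapse onto the single draw
  single <- run_grid(sim_config(n_grid = 50, k_grid = 2, reps = 1, seed = 6))
  expect_equal(single$mean, single$q50)
  expect_equal(single$q05, single$q95)
  expect_error(sim_config(n_grid = c(10, 50), k_grid = 2:10), "twice")
})

test_that("the plateau detector finds the smallest adequate n", {
  ns <- seq(50, 250, by = 25)
  means <- c(0.30, 0.35, 0.40, 0.45, 0.45, 0.451, 0.452, 0.451, 0.452)
  grid <- data.frame(n = ns, k = 3, mean = means)
  rec <- recommend_sample_size(grid, k_max_of_interest = 3, plateau_tol = 0.01)
  expect_equal(rec$recommended_n, 125)
  # a tolerance wider than the whole range returns the smallest n
  rec <- recommend_sample_size(grid, k_max_of_interest = 3, plateau_tol = 1)
  expect_equal(rec$recommended_n, 50)
  # conservative max over k
  grid2 <- rbind(grid, data.frame(n = ns, k = 2, mean = pmin(means + 0.1, 0.46)))
  rec <- recommend_sample_size(grid2, k_max_of_interest = 3, plateau_tol = 0.01)
  expect_equal(nrow(rec$per_k), 2)
  expect_equal(rec$recommended_n, max(rec$per_k$plateau_n))
})
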