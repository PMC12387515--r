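test_that("quartile-matched log-normal reproduces the reported quantiles", {
  # hand-evaluated quantile-matching formula
  par <- fit_quartile_lognormal(1, 0.5, 2)
  expect_equal(unname(par["mu"]), 0, tolerance = 1e-12)
  expect_equal(unname(par["sigma"]), 1.0276615, tolerance = 1e-6)

  par <- fit_quartile_lognormal(21.33, 19.11, 23.41)
  expect_equal(unname(par["mu"]), 3.0601145, tolerance = 1e-6)
  expect_equal(unname(par["sigma"]), 0.1504482, tolerance = 1e-6)
  # the fitted distribution's median is exact by construction
  expect_equal(qlnorm(0.5, par["mu"], par["sigma"]), 21.33, tolerance = 1e-12)

  expect_error(fit_quartile_lognormal(exp(1), exp(1), exp(1)), "q1 < median")
  expect_error(fit_quartile_lognormal(1, -1, 2), "q1")
})

test_that("gaussian copula hits independence and comonotone limits", {
  targets <- diag(3)
  u <- gaussian_copula_sample(targets, 10000, seed = 7)
  expect_true(all(abs(cor(u, method = "spearman")[upper.tri(targets)]) < 0.05))
  # uniform margins
  expect_true(all(abs(colMeans(u) - 0.5) < 0.02))

  targets <- matrix(c(1, 1, 1, 1), 2)
  u <- gaussian_copula_sample(targets, 500, seed = 7)
  expect_equal(u[, 1], u[, 2], tolerance = 1e-6)
})

test_that("copula rejects a non-positive-definite target unless repaired", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(gaussian_copula_sample(bad, 10, seed = 1), "positive definite")
  skip_if_not_installed("Matrix")
  u <- gaussian_copula_sample(bad, 50, seed = 1, repair = TRUE)
  expect_equal(dim(u), c(50, 3))
})

test_that("largest-remainder apportionment matches enumeration and the cohort defaults", {
  expect_identical(largest_remainder(127, c(49, 32, 46) / 127), c(49L, 32L, 46L))
  expect_identical(largest_remainder(125, rep(1, 3)), c(42L, 42L, 41L))
  set.seed(3)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    w <- runif(k)
    n <- sample(5:200, 1)
    a <- largest_remainder(n, w)
    expect_identical(sum(a), as.integer(n))
    # apportionment stays within one unit of the exact quota
    expect_true(all(abs(a - n * w / sum(w)) < 1))
  }
})

test_that("default synthetic cohort has the expected sizes, ranges and determinism", {
  cfg <- cohort_config(n = 127, seed = 42)
  cohort <- generate_cohort(cfg)
  expect_identical(unname(attr(cohort, "cluster_sizes")), c(49L, 32L, 46L))
  expect_identical(as.integer(table(cohort$true_cluster)[c("1", "2", "3")]),
    c(49L, 32L, 46L))
  expect_true(all(cohort$fss_score >= 1 & cohort$fss_score <= 7))
  expect_true(all(cohort$phq9_score %in% 0:27))
  expect_true(all(cohort$isi_score %in% 0:28))
  expect_true(all(cohort$age > 0) && all(cohort$bmi > 0))
  expect_identical(generate_cohort(cfg), cohort)
  # different seed, different draws
  expect_false(identical(generate_cohort(cohort_config(n = 127, seed = 43)), cohort))
  expect_error(cohort_config(n = 2), ">= 3")
})

test_that("single-cluster margins recover their generating parameters", {
  spec <- default_cluster_specs()[[1]]
  spec$weight <- 1
  cohort <- generate_cohort(cohort_config(
    n = 4000, cluster_specs = list(spec), seed = 9
  ))
  expect_equal(mean(cohort$age), 22.6, tolerance = 0.01) # relative
  expect_equal(sd(cohort$age), 3.1, tolerance = 0.03)
  expect_equal(mean(cohort$fss_score), 2.7, tolerance = 0.02)
  expect_equal(sd(cohort$fss_score), 0.8, tolerance = 0.04)
  expect_equal(median(cohort$bmi), 20.0, tolerance = 0.02)
  expect_equal(median(cohort$years_dx), 8.6, tolerance = 0.03)
  expect_equal(mean(cohort$sex == "male"), 0.408, tolerance = 0.1)
})

test_that("item emission composes totals uniformly and validates bounds", {
  expect_identical(emit_items(27, 9, 0, 3), rep(3L, 9))
  expect_identical(emit_items(0, 9, 0, 3), rep(0L, 9))
  expect_error(emit_items(28, 9, 0, 3), "impossible")
  expect_error(emit_items(8, 9, 1, 7), "impossible")
  set.seed(21)
  for (i in 1:30) {
    tot <- sample(0:28, 1)
    items <- emit_items(tot, 7, 0, 4, seed = i)
    expect_identical(sum(items), as.integer(tot))
    expect_true(all(items >= 0 & items <= 4))
  }
})

test_that("cohort item columns re-aggregate to the stored totals", {
  cohort <- generate_cohort(cohort_config(n = 60, seed = 5, item_level = TRUE))
  expect_equal(rowSums(cohort[paste0("phq9_", 1:9)]), cohort$phq9_score,
    ignore_attr = TRUE
  )
  expect_equal(rowSums(cohort[paste0("isi_", 1:7)]), cohort$isi_score,
    ignore_attr = TRUE
  )
  # FSS item means agree with the continuous score up to rounding of 9*score
  expect_true(all(
    abs(rowMeans(cohort[paste0("fss_", 1:9)]) - cohort$fss_score) <= 1 / 18 + 1e-9
  ))
  expect_true(all(as.matrix(cohort[paste0("fss_", 1:9)]) %in% 1:7))
})

test_that("cohort writer emits CSV plus a truth file", {
  cohort <- generate_cohort(cohort_config(n = 20, seed = 2))
  path <- tempfile(fileext = ".csv")
  written <- write_cohort(cohort, path)
  expect_length(written, 2)
  back <- read.csv(written[1])
  expect_equal(nrow(back), 20)
  truth <- read.csv(written[2])
  expect_identical(names(truth), c("id", "true_cluster"))
})

test_that("YAML cohort config round-trips through the reader", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n: 60", "seed: 7", "item_level: false",
    "rank_corr_targets:",
    "  - [fss, phq9, 0.5]",
    "  - [age, bmi, 0.3]"
  ), tmp)
  cfg <- read_cohort_config(tmp)
  expect_identical(cfg$n, 60L)
  expect_equal(cfg$rank_corr_targets["fss", "phq9"], 0.5)
  expect_equal(cfg$rank_corr_targets["age", "bmi"], 0.3)
  expect_equal(cfg$rank_corr_targets["fss", "isi"], 0)
  expect_s3_class(generate_cohort(cfg), "data.frame")
})
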