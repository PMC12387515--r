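test_that("Spearman matrix is monotone-invariant with hand-checkable values", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 2, 3, 5, 4)
  df <- data.frame(x = x, y = y)
  sm <- spearman_matrix(df, c("x", "y"))
  expect_equal(sm$rho["x", "y"], 0.9) # 1 - 6*2/(5*24)
  expect_equal(diag(sm$rho), c(x = 1, y = 1))

  # monotone transform invariance
  df2 <- data.frame(x = exp(x), y = y^3)
  sm2 <- spearman_matrix(df2, c("x", "y"))
  expect_equal(sm2$rho["x", "y"], sm$rho["x", "y"], tolerance = 1e-12)
  expect_equal(
    spearman_matrix(data.frame(x = x, y = exp(x)), c("x", "y"))$rho["x", "y"], 1
  )

  expect_error(
    spearman_matrix(data.frame(x = x, y = rep(2, 5)), c("x", "y")),
    "constant variable: y"
  )
  expect_error(spearman_matrix(df[1:3, ], c("x", "y")), "at least 4")
})

test_that("BH adjustment matches the step-up definition on random vectors", {
  expect_equal(bh_adjust(0.03)$adjusted, 0.03)
  out <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(out$reject))
  out <- bh_adjust(rep(1, 6))
  expect_false(any(out$reject))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(51)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    got <- bh_adjust(p, alpha = 0.05)
    want <- oracle_bh(p, alpha = 0.05)
    expect_equal(got$adjusted, want$adjusted, tolerance = 1e-12)
    expect_identical(got$reject, want$reject)
    expect_true(all(got$adjusted >= p - 1e-15))
  }
})

test_that("partial Spearman equals the rank-residual oracle and its limits", {
  set.seed(52)
  # worked small instance against the independent residual-regression oracle
  for (i in 1:50) {
    n <- sample(6:12, 1)
    x <- rnorm(n)
    y <- x + rnorm(n)
    z <- 0.5 * x + rnorm(n)
    got <- partial_spearman(x, y, z)
    expect_equal(got$rho, oracle_partial_spearman(x, y, z), tolerance = 1e-9)
    expect_equal(got$df, n - 3)
  }
  # independent control barely changes the plain correlation
  n <- 2000
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n)
  z <- rnorm(n)
  plain <- cor(rank(x), rank(y))
  expect_lt(abs(partial_spearman(x, y, z)$rho - plain), 0.05)
  # a control that fully explains y drives the partial correlation to zero
  z2 <- y + rnorm(n, sd = 1e-3)
  expect_lt(abs(partial_spearman(x, y, z2)$rho), 0.05)
  # an exactly collinear control is singular
  expect_error(partial_spearman(x, y, y), "singular")
  expect_error(partial_spearman(1:4, 1:4, 4:1), "at least 5")
})

test_that("Mann-Whitney U matches enumeration, symmetry and the pairing identity", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_identical(mw$method, "exact")

  mw <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw$U, 4.5) # ties at mid-rank

  set.seed(53)
  for (i in 1:40) {
    x <- sample(1:20, sample(2:8, 1), replace = TRUE)
    y <- sample(1:20, sample(2:8, 1), replace = TRUE)
    mw_xy <- mann_whitney_u(x, y)
    mw_yx <- mann_whitney_u(y, x)
    expect_equal(mw_xy$U, oracle_mwu(x, y), tolerance = 1e-12)
    expect_equal(mw_xy$U + mw_yx$U, length(x) * length(y))
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("tertile stratification splits at the empirical 2/3 age quantile", {
  cohort <- score_cohort(generate_cohort(cohort_config(n = 127, seed = 54)))
  st <- tertile_stratified_comparison(cohort)
  expect_equal(st$threshold, quantile(cohort$age, 2 / 3, type = 7, names = FALSE))
  expect_equal(st$n_upper, sum(cohort$age >= st$threshold))
  expect_equal(sum(st$group_sizes), st$n_upper)
  expect_identical(
    st$table$variable, c("phq9_score", "isi_score", "bmi", "years_dx")
  )
  expect_true(all(st$table$U >= 0 &
    st$table$U <= st$group_sizes["high"] * st$group_sizes["low"]))

  # all-low-fatigue cohort: descriptives with a warning, no test
  low <- cohort
  low$fss_score <- pmin(low$fss_score, 4.5)
  expect_warning(st2 <- tertile_stratified_comparison(low), "empty")
  expect_true(all(is.na(st2$table$p_value)))
})

test_that("the association battery is coherent across its components", {
  cohort <- score_cohort(generate_cohort(cohort_config(n = 127, seed = 55)))
  rep <- associations(cohort)
  expect_equal(nrow(rep$pairs), choose(6, 2))
  expect_true(all(rep$pairs$p_adjusted >= rep$pairs$p - 1e-15))
  expect_identical(rep$pairs$reject, rep$pairs$p_adjusted <= rep$alpha)
  expect_equal(rep$rho, t(rep$rho))
  expect_equal(diag(rep$rho), setNames(rep(1, 6), colnames(rep$rho)))
  expect_identical(rep$partial$pair, c("fss_score~phq9_score", "fss_score~isi_score"))
  # strong built-in dependence survives age adjustment in sign
  expect_gt(rep$partial$rho[1], 0)
  expect_s3_class(rep$stratified, "stratified_comparison")
})
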