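test_that("PHQ-9 and ISI banding is exhaustive, exclusive and boundary-inclusive", {
  th <- instrument_thresholds()
  phq_expected <- rep(th$phq9_labels, times = c(5, 5, 5, 5, 8)) # 0..27
  for (s in 0:27) {
    expect_identical(score_phq9(score = s)$category, phq_expected[s + 1])
  }
  isi_expected <- rep(th$isi_labels, times = c(8, 7, 7, 7)) # 0..28
  for (s in 0:28) {
    expect_identical(score_isi(score = s)$category, isi_expected[s + 1])
  }
  # each breakpoint maps to the upper band, breakpoint - 1 to the lower
  for (b in th$phq9_breaks) {
    expect_false(identical(
      score_phq9(score = b)$category, score_phq9(score = b - 1)$category
    ))
  }
})

test_that("FSS classification respects the 4.67 clinical cut-off over a fine grid", {
  for (s in seq(1, 7, by = 0.01)) {
    expect_identical(
      score_fss(score = s)$category == "clinically relevant fatigue",
      s >= 4.67
    )
  }
  expect_identical(score_fss(score = 4.67)$category, "clinically relevant fatigue")
  expect_identical(
    score_fss(score = 4.67 - 1e-9)$category, "not clinically relevant"
  )
})

test_that("instrument scores are the documented item aggregates", {
  expect_equal(score_fss(rep(7L, 9))$score, 7)
  expect_identical(score_fss(rep(7L, 9))$category, "clinically relevant fatigue")
  expect_equal(score_fss(rep(4L, 9))$score, 4)
  expect_identical(score_fss(rep(4L, 9))$category, "not clinically relevant")
  expect_equal(score_phq9(rep(3L, 9))$score, 27L)
  expect_identical(score_phq9(rep(3L, 9))$category, "severe depression")
  expect_identical(score_phq9(rep(0L, 9))$category, "no depressive symptoms")
  expect_identical(score_isi(rep(0L, 7))$category, "no clinically significant insomnia")
  expect_identical(score_isi(rep(4L, 7))$score, 28L)
  expect_identical(score_isi(rep(4L, 7))$category, "severe clinical insomnia")
})

test_that("scoring is permutation-invariant in the items", {
  set.seed(11)
  for (rep in 1:20) {
    fss_items <- sample(1:7, 9, replace = TRUE)
    phq_items <- sample(0:3, 9, replace = TRUE)
    isi_items <- sample(0:4, 7, replace = TRUE)
    expect_equal(
      score_fss(sample(fss_items))$score, score_fss(fss_items)$score
    )
    expect_equal(
      score_phq9(sample(phq_items))$score, score_phq9(phq_items)$score
    )
    expect_equal(
      score_isi(sample(isi_items))$score, score_isi(isi_items)$score
    )
  }
})

test_that("invalid items are rejected with the offending index named", {
  expect_error(score_fss(rep(4L, 8)), "exactly 9 items")
  expect_error(score_fss(c(rep(4L, 4), 8L, rep(4L, 4))), "item 5")
  expect_error(score_phq9(c(rep(1L, 6), 4L, 1L, 1L)), "item 7")
  expect_error(score_isi(c(0L, -1L, rep(2L, 5))), "item 2")
  expect_error(score_isi(c(0L, NA, rep(2L, 5))), "item 2")
  expect_error(score_phq9(score = 28), "0..27")
  expect_error(score_isi(score = 2.5), "integer")
})

test_that("item/total disagreement rejects the record", {
  expect_error(score_fss(rep(4L, 9), score = 4.5), "disagrees")
  expect_silent(score_fss(rep(4L, 9), score = 4))
  expect_error(score_phq9(rep(1L, 9), score = 10), "disagrees")
})

test_that("BMI is weight over height squared with positivity checks", {
  expect_equal(compute_bmi(80, 2.0), 20)
  expect_equal(compute_bmi(70, 1.87), 70 / 1.87^2, tolerance = 1e-12)
  expect_error(compute_bmi(0, 1.8), "positive")
  expect_error(compute_bmi(70, 0), "positive")
})

test_that("score_cohort emits all scored columns from items or totals", {
  set.seed(5)
  n <- 8
  df <- data.frame(id = paste0("P", 1:n))
  for (i in 1:9) df[[paste0("fss_", i)]] <- sample(1:7, n, TRUE)
  for (i in 1:9) df[[paste0("phq9_", i)]] <- sample(0:3, n, TRUE)
  for (i in 1:7) df[[paste0("isi_", i)]] <- sample(0:4, n, TRUE)
  df$weight <- runif(n, 55, 90)
  df$height <- runif(n, 1.6, 1.95)
  scored <- score_cohort(df)
  expect_true(all(c(
    "fss_score", "fss_clinical", "phq9_score", "phq9_band", "isi_score",
    "isi_band", "bmi"
  ) %in% names(scored)))
  expect_equal(scored$fss_score, rowMeans(df[paste0("fss_", 1:9)]))
  expect_equal(scored$phq9_score, rowSums(df[paste0("phq9_", 1:9)]))
  expect_equal(scored$bmi, df$weight / df$height^2)

  # totals-only cohort works too; a broken row is named
  tot <- data.frame(
    fss_score = c(3.2, 5.1), phq9_score = c(4, 30), isi_score = c(2, 3),
    bmi = c(21, 24)
  )
  expect_error(score_cohort(tot), "row 2")
  tot$phq9_score[2] <- 12
  expect_identical(score_cohort(tot)$phq9_band[2], "mild depression")
})
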