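test_that("Ward tree matches hand-enumerable cases", {
  # two points at distance 3: one merge at height 3
  tr <- ward_tree(matrix(c(0, 3), ncol = 1))
  expect_equal(tr$hclust$height, 3)

  # two tight pairs far apart: the pairs merge first
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  tr <- ward_tree(pts)
  expect_equal(tr$hclust$height[1:2], c(1, 1))
  cl <- cut_tree(tr, 2)
  expect_same_partition(cl, c(1, 1, 2, 2))

  expect_error(ward_tree(matrix(1, 1, 1)), "at least 2")
})

test_that("Ward merge heights are monotone non-decreasing", {
  set.seed(31)
  pts <- matrix(rnorm(200), ncol = 2)
  tr <- ward_tree(pts)
  expect_true(all(diff(tr$hclust$height) >= -1e-12))
})

test_that("tree cuts produce the requested number of clusters", {
  set.seed(32)
  pts <- matrix(rnorm(40), ncol = 2)
  tr <- ward_tree(pts)
  expect_equal(length(unique(cut_tree(tr, 1))), 1)
  expect_equal(length(unique(cut_tree(tr, 20))), 20) # all singletons
  for (k in 2:6) expect_equal(length(unique(cut_tree(tr, k))), k)
  expect_error(cut_tree(tr, 21), "exceed")
  expect_error(cut_tree(tr, 0), ">= 1")
})

test_that("silhouettes match the hand formula and the brute-force oracle", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  s <- silhouette_scores(pts, c(1, 1, 2, 2))
  expect_equal(s$mean, (9.5 / 10.5 + 8.5 / 9.5) / 2, tolerance = 1e-9)

  # singleton convention: two singletons score zero
  s <- silhouette_scores(matrix(c(0, 10), ncol = 1), c(1, 2))
  expect_equal(s$mean, 0)

  expect_error(silhouette_scores(pts, c(1, 1, 1, 1)), "two clusters")

  set.seed(33)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    k <- sample(2:3, 1)
    pts <- matrix(rnorm(2 * n), ncol = 2)
    lab <- sample(rep_len(seq_len(k), n))
    expect_equal(
      silhouette_scores(pts, lab)$widths,
      oracle_silhouette(pts, lab),
      tolerance = 1e-12, ignore_attr = TRUE
    )
  }
})

test_that("k evaluation identifies well-separated structure and honours overrides", {
  sim <- simulate_clusters(120, 3, d = 6, seed = 34)
  ke <- evaluate_k_range(scale(sim$x), 2, 8)
  expect_equal(attr(ke, "optimal_k"), 3)
  expect_equal(attr(ke, "chosen_k"), 3)
  expect_equal(ke$k, 2:8)
  expect_true(all(abs(ke$mean_silhouette) <= 1))

  ke2 <- evaluate_k_range(scale(sim$x), 2, 8, choose_k = 5)
  expect_equal(attr(ke2, "chosen_k"), 5)
  expect_match(attr(ke2, "rationale"), "override")
  expect_error(evaluate_k_range(scale(sim$x), 2, 8, choose_k = 12), "range")

  ke3 <- evaluate_k_range(scale(sim$x), 2, 2)
  expect_equal(nrow(ke3), 1)
})

test_that("fatigue-ordered relabeling is canonical and tie-stable", {
  cl <- c(1, 1, 2, 2, 3, 3)
  fss <- c(5, 5, 2, 2, 3.5, 3.5) # cluster 2 lowest, 3 middle, 1 highest
  out <- relabel_by_fss(cl, fss)
  expect_identical(out, c(3L, 3L, 1L, 1L, 2L, 2L))
  means <- tapply(fss, out, mean)
  expect_true(all(diff(means) > 0))
  # FSS tie broken by ascending PHQ-9
  out <- relabel_by_fss(c(1, 2), fss = c(4, 4), phq9 = c(5, 1))
  expect_identical(out, c(2L, 1L))
  expect_error(relabel_by_fss(c(1, 2), fss = 1), "same length")
})

test_that("Newick export reproduces topology and heights", {
  tr <- ward_tree(matrix(c(0, 3), ncol = 1))
  expect_identical(export_newick(tr, labels = c("A", "B")), "(A:3,B:3);")

  skip_if_not_installed("ape")
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  tr <- ward_tree(pts)
  nwk <- export_newick(tr)
  ph <- ape::read.tree(text = nwk)
  expect_true(ape::is.ultrametric(ph, tol = 1e-8))
  # merge heights round-trip (branching times = merge heights)
  expect_equal(
    sort(unname(ape::branching.times(ph))), sort(tr$hclust$height),
    tolerance = 1e-9
  )
  # the two tight pairs are sister clades
  parts <- ape::prop.part(ph)
  sets <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(list(c("1", "2")) %in% sets || any(sapply(sets, identical, c("1", "2"))))
  expect_true(any(sapply(sets, identical, c("3", "4"))))

  # round-trip on a random tree
  set.seed(35)
  tr <- ward_tree(matrix(rnorm(24), ncol = 2))
  ph <- ape::read.tree(text = export_newick(tr))
  expect_equal(
    sort(unname(ape::branching.times(ph))), sort(tr$hclust$height),
    tolerance = 1e-9
  )
})
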