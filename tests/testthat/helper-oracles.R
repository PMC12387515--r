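# Independent brute-force reference implementations used to cross-check the
# package's statistics. These deliberately share no code with the package
# internals: plain loops and textbook formulas only.

# naive Ward agglomeration on raw coordinates; merge cost is the increase in
# within-cluster sum of squares, reported on the sqrt(2 * delta-SSE) height
# scale (the Euclidean Ward height convention). Returns the sorted merge
# heights and the partition at every k.
oracle_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  members <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(members) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(members)) {
      for (j in seq_len(i - 1)) {
        a <- members[[i]]
        b <- members[[j]]
        ma <- colMeans(x[a, , drop = FALSE])
        mb <- colMeans(x[b, , drop = FALSE])
        cost <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ma - mb)^2)
        if (cost < best[1] - 1e-12) best <- c(cost, j, i) # smallest pair first
      }
    }
    i <- best[3]
    j <- best[2]
    heights <- c(heights, sqrt(2 * best[1]))
    members[[j]] <- c(members[[j]], members[[i]])
    members[[i]] <- NULL
    k <- length(members)
    part <- integer(n)
    for (ci in seq_along(members)) part[members[[ci]]] <- ci
    partitions[[k]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# textbook silhouette, double loop
oracle_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  dm <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) {
      s[i] <- 0
      next
    }
    a <- mean(dm[i, setdiff(own, i)])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(dm[i, labels == cl]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Pearson chi-square by explicit double loop
oracle_chisq <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  x2 <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- rs[i] * cs[j] / n
      x2 <- x2 + (tab[i, j] - e)^2 / e
    }
  }
  list(statistic = x2, df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

# Benjamini-Hochberg from the step-up definition
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  # rejection set from the threshold definition: largest k with
  # p_(k) <= k * alpha / m, reject all p at or below p_(k)
  ks <- which(p[o] <= seq_len(m) * alpha / m)
  reject <- rep(FALSE, m)
  if (length(ks)) reject[o[seq_len(max(ks))]] <- TRUE
  list(adjusted = adjusted, reject = reject)
}

# Mann-Whitney U by pair counting (ties count one half)
oracle_mwu <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}

# partial Spearman as the correlation of rank-regression residuals
oracle_partial_spearman <- function(x, y, z) {
  z <- as.matrix(z)
  rx <- rank(x)
  ry <- rank(y)
  rz <- apply(z, 2, rank)
  ex <- stats::residuals(stats::lm(rx ~ rz))
  ey <- stats::residuals(stats::lm(ry ~ rz))
  stats::cor(ex, ey)
}

# canonical form of a partition for label-free comparison
partition_signature <- function(labels) {
  f <- as.integer(factor(labels, levels = unique(labels)))
  paste(f, collapse = ".")
}

expect_same_partition <- function(a, b) {
  expect_identical(partition_signature(a), partition_signature(b))
}
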