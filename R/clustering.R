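#' Ward minimum-variance linkage tree
#'
#' Agglomerative clustering with Ward's criterion on Euclidean distances
#' (the `ward.D2` update, i.e. the merge height for two singletons at
#' distance d is d, and in general the square root of twice the increase in
#' within-cluster sum of squares). Merge heights are non-decreasing;
#' duplicate points produce zero-height merges.
#'
#' @param points Numeric matrix, one row per observation (typically the
#'   two t-SNE coordinates).
#' @return An object of class `ward_tree` wrapping the `hclust` result,
#'   with leaf labels taken from the rownames of `points` (or `1..n`).
#' @export
ward_tree <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points")
  if (any(!is.finite(points))) stop("points must be finite")
  labels <- rownames(points) %||% as.character(seq_len(nrow(points)))
  hc <- stats::hclust(stats::dist(points), method = "ward.D2")
  hc$labels <- labels
  structure(list(hclust = hc, n = nrow(points)), class = "ward_tree")
}

#' @export
print.ward_tree <- function(x, ...) {
  cat(sprintf(
    "Ward linkage tree: %d leaves, merge heights %.3g .. %.3g\n",
    x$n, min(x$hclust$height), max(x$hclust$height)
  ))
  invisible(x)
}

#' Cut a Ward tree into k clusters
#'
#' Removes the `k - 1` highest merges, yielding exactly `k` non-empty
#' clusters.
#'
#' @param tree A [ward_tree()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster assignments (named by leaf labels).
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "ward_tree"))
  assert_count(k, "k")
  if (k > tree$n) stop("k cannot exceed the number of leaves")
  stats::cutree(tree$hclust, k = k)
}

#' Silhouette widths of a clustering
#'
#' For each point, `s = (b - a) / max(a, b)` where `a` is its mean distance
#' to the other members of its own cluster and `b` the smallest mean
#' distance to any other cluster; members of singleton clusters get `s = 0`
#' (Rousseeuw's convention). Euclidean distances.
#'
#' @param points Numeric matrix of coordinates.
#' @param assignments Cluster labels (at least two non-empty clusters).
#' @return A list with `widths` (per-point silhouettes) and `mean`.
#' @export
silhouette_scores <- function(points, assignments) {
  points <- as.matrix(points)
  assignments <- as.integer(factor(assignments))
  if (length(assignments) != nrow(points)) {
    stop("assignments must match the number of points")
  }
  if (length(unique(assignments)) < 2) {
    stop("silhouette needs at least two clusters")
  }
  sil <- cluster::silhouette(assignments, stats::dist(points))
  widths <- if (is.matrix(sil)) {
    sil[, "sil_width"]
  } else {
    # all-singleton partition: every width is 0 by the singleton convention
    rep(0, nrow(points))
  }
  list(widths = widths, mean = mean(widths))
}

#' Evaluate cluster solutions over a range of k
#'
#' Cuts one Ward tree at every k in the range and scores each partition by
#' its mean silhouette width on the same coordinates that were clustered.
#' The silhouette-optimal k is reported; the *chosen* k is the explicit
#' `choose_k` override when given (model selection in practice weighs
#' interpretability alongside the silhouette), otherwise the optimal one.
#'
#' @param points Coordinate matrix (e.g. the 2-D embedding).
#' @param k_min,k_max Range of cluster counts to evaluate (`k_max < n`).
#' @param choose_k Optional override for the selected k.
#' @return An object of class `k_evaluation`: data frame `k, mean_silhouette,
#'   sizes` plus attributes `optimal_k`, `chosen_k`, `tree`, `rationale`.
#' @export
evaluate_k_range <- function(points, k_min = 2, k_max = 10,
                             choose_k = NULL) {
  points <- as.matrix(points)
  if (k_max >= nrow(points)) stop("k_max must be smaller than n")
  if (k_min < 2) stop("k_min must be at least 2")
  tree <- ward_tree(points)
  ks <- seq.int(k_min, k_max)
  rows <- lapply(ks, function(k) {
    cl <- cut_tree(tree, k)
    data.frame(
      k = k, mean_silhouette = silhouette_scores(points, cl)$mean,
      sizes = paste(sort(tabulate(cl), decreasing = TRUE), collapse = "/")
    )
  })
  out <- do.call(rbind, rows)
  optimal <- out$k[which.max(out$mean_silhouette)]
  chosen <- if (is.null(choose_k)) optimal else as.integer(choose_k)
  if (!(chosen %in% ks)) stop("choose_k must lie within the evaluated range")
  structure(out,
    class = c("k_evaluation", "data.frame"),
    optimal_k = optimal, chosen_k = chosen, tree = tree,
    rationale = if (chosen == optimal) {
      sprintf("k = %d maximises the mean silhouette", chosen)
    } else {
      sprintf(
        "k = %d chosen by explicit override (silhouette-optimal k = %d)",
        chosen, optimal
      )
    }
  )
}

#' @export
print.k_evaluation <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(attr(x, "rationale"), "\n")
  invisible(x)
}

#' Relabel clusters by ascending mean fatigue severity
#'
#' Makes cluster identities stable and clinically ordered: cluster 1 is the
#' lowest-fatigue group and cluster k the highest, regardless of the order
#' in which the dendrogram produced them. Ties in mean FSS are broken by
#' ascending mean PHQ-9, then by original label.
#'
#' @param assignments Cluster labels.
#' @param fss Fatigue severity scores, same length.
#' @param phq9 Optional depression scores for tie-breaking.
#' @return Integer assignments in `1..k`, ordered by mean FSS.
#' @export
relabel_by_fss <- function(assignments, fss, phq9 = NULL) {
  if (length(assignments) != length(fss)) {
    stop("assignments and fss must have the same length")
  }
  f <- factor(assignments)
  mean_fss <- tapply(fss, f, mean)
  mean_phq <- if (is.null(phq9)) rep(0, nlevels(f)) else tapply(phq9, f, mean)
  ord <- order(mean_fss, mean_phq, levels(f))
  map <- integer(nlevels(f))
  map[ord] <- seq_len(nlevels(f))
  out <- map[as.integer(f)]
  names(out) <- names(assignments)
  out
}

#' Serialize a Ward tree as a Newick string
#'
#' Rooted Newick with branch lengths equal to merge-height differences
#' (leaves sit at height 0), so the string round-trips to the same topology
#' and merge heights. Two leaves merged at height 3 give `"(A:3,B:3);"`.
#'
#' @param tree A [ward_tree()].
#' @param labels Optional leaf labels (default: the tree's own).
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string (terminated by `;`).
#' @export
export_newick <- function(tree, labels = NULL, digits = 10) {
  stopifnot(inherits(tree, "ward_tree"))
  hc <- tree$hclust
  labels <- labels %||% hc$labels
  if (length(labels) != tree$n) stop("need one label per leaf")
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  node_str <- function(idx, parent_h) {
    # idx < 0: leaf -idx; idx > 0: merge row idx
    if (idx < 0) {
      sprintf("%s:%s", labels[-idx], fmt(parent_h))
    } else {
      h <- hc$height[idx]
      sprintf(
        "(%s,%s):%s",
        node_str(hc$merge[idx, 1], h), node_str(hc$merge[idx, 2], h),
        fmt(parent_h - h)
      )
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  sprintf(
    "(%s,%s);",
    node_str(hc$merge[root, 1], h), node_str(hc$merge[root, 2], h)
  )
}
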