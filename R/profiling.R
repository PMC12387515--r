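#' Choose the between-group test for a continuous variable
#'
#' Normality gate: Shapiro-Wilk within each group at level `alpha`; classic
#' one-way ANOVA is used only when every group passes, otherwise the
#' Kruskal-Wallis rank-sum test. Groups with fewer than 3 observations
#' cannot be tested for normality and force the non-parametric branch (with
#' a warning).
#'
#' @param values Numeric vector.
#' @param groups Grouping factor (>= 2 non-empty groups).
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return `"anova"` or `"kruskal"`.
#' @export
choose_continuous_test <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  split_vals <- split(values, droplevels(groups))
  if (any(lengths(split_vals) < 3)) {
    warning("group with < 3 observations: falling back to Kruskal-Wallis")
    return("kruskal")
  }
  # shapiro.test caps at n = 5000; subsample deterministically beyond that
  p_norm <- vapply(split_vals, function(v) {
    if (length(v) > 5000) v <- v[seq(1, length(v), length.out = 5000)]
    if (stats::sd(v) == 0) {
      return(0)
    } # degenerate: clearly non-normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  if (all(p_norm >= alpha)) "anova" else "kruskal"
}

# run the gated continuous test, returning a group_test_result row
continuous_group_test <- function(variable, values, groups, alpha = 0.05) {
  groups <- droplevels(factor(groups))
  test <- choose_continuous_test(values, groups, alpha)
  split_vals <- split(values, groups)
  if (test == "anova") {
    ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    stat <- unname(ft$statistic)
    df <- paste(round(ft$parameter, 2), collapse = ", ")
    p <- ft$p.value
    summaries <- vapply(split_vals, function(v) {
      sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
    }, character(1))
    test_name <- "ANOVA"
  } else {
    kt <- stats::kruskal.test(values, groups)
    stat <- unname(kt$statistic)
    df <- as.character(unname(kt$parameter))
    p <- kt$p.value
    summaries <- vapply(split_vals, function(v) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      sprintf("%.1f (%.1f–%.1f)", q[2], q[1], q[3])
    }, character(1))
    test_name <- "Kruskal-Wallis"
  }
  group_result(variable, test_name, stat, df, p, summaries)
}

group_result <- function(variable, test, statistic, df, p, summaries) {
  row <- data.frame(
    variable = variable, test = test, statistic = statistic, df = df,
    p_value = p, stringsAsFactors = FALSE
  )
  for (g in names(summaries)) row[[paste0("group_", g)]] <- summaries[[g]]
  row
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson X^2 = sum((O - E)^2 / E) without continuity correction.
#' Expected counts of zero are an error; when more than 20% of cells have
#' expected counts below 5 a warning recommends an exact test.
#'
#' @param tab Two-dimensional integer contingency table.
#' @param variable Variable name carried into the result.
#' @return A one-row data frame: `variable, test, statistic, df, p_value`
#'   plus per-group `count (%)` summaries.
#' @export
chi_square_counts <- function(tab, variable = "variable") {
  tab <- as.matrix(tab)
  if (any(tab != round(tab)) || any(tab < 0)) {
    stop("contingency table must hold non-negative integer counts")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("expected count of zero: remove empty rows/columns first")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (mean(expected < 5) > 0.2) {
    warning(
      "more than 20% of expected counts are below 5; ",
      "an exact test would be more appropriate"
    )
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  col_tot <- colSums(tab)
  summaries <- vapply(seq_len(ncol(tab)), function(j) {
    paste(sprintf("%d (%.1f%%)", tab[, j], 100 * tab[, j] / col_tot[j]),
      collapse = "; "
    )
  }, character(1))
  names(summaries) <- colnames(tab) %||% as.character(seq_len(ncol(tab)))
  group_result(
    variable, "chi-square", unname(res$statistic),
    as.character(unname(res$parameter)), res$p.value, summaries
  )
}

#' Default profiling variable manifest
#'
#' @return Data frame `variable, type` covering the demographic, clinical
#'   and psychometric variables summarised per cluster.
#' @export
default_profile_manifest <- function() {
  data.frame(
    variable = c(
      "age", "years_dx", "bmi", "phq9_score", "isi_score", "fss_score",
      "sex", "phq9_band", "isi_band", "fss_clinical"
    ),
    type = c(rep("continuous", 6), rep("categorical", 4)),
    stringsAsFactors = FALSE
  )
}

#' Profile clusters with the gated test battery
#'
#' Produces per-cluster summaries and between-cluster tests for each
#' manifest variable: normality-gated ANOVA (mean +/- SD) or
#' Kruskal-Wallis (median (q1-q3)) for continuous variables, Pearson
#' chi-square on counts (%) for categorical ones. Banded instrument
#' categories with empty rows across all clusters are summarised on the
#' observed categories only. The proportion with clinically relevant
#' fatigue is always tested by chi-square on the 2 x k indicator table
#' when `fss_clinical` is available.
#'
#' @param cohort Scored cohort data frame.
#' @param assignments Cluster labels covering every row.
#' @param manifest Data frame `variable, type`
#'   (default [default_profile_manifest()], restricted to columns present).
#' @param alpha Normality-gate level.
#' @return An object of class `profile_report`: data frame of test rows with
#'   attributes `cluster_labels` (semantic labels via [label_clusters()]),
#'   `fss_means`, `n`.
#' @export
profile_clusters <- function(cohort, assignments,
                             manifest = NULL, alpha = 0.05) {
  if (length(assignments) != nrow(cohort)) {
    stop("assignments must cover the whole cohort")
  }
  groups <- factor(assignments)
  if (nlevels(droplevels(groups)) < 2) {
    stop("all points fall in a single cluster: no between-group test possible")
  }
  if (is.null(manifest)) {
    # default manifest adapts to whichever scored columns exist
    manifest <- default_profile_manifest()
    manifest <- manifest[manifest$variable %in% names(cohort), , drop = FALSE]
  } else {
    unknown <- setdiff(manifest$variable, names(cohort))
    if (length(unknown)) {
      stop("unknown variable(s): ", paste(unknown, collapse = ", "))
    }
  }
  if (!nrow(manifest)) stop("no manifest variables present in the cohort")
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    v <- manifest$variable[i]
    if (manifest$type[i] == "continuous") {
      continuous_group_test(v, cohort[[v]], groups, alpha)
    } else {
      tab <- table(cohort[[v]], groups)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (nrow(tab) < 2) {
        group_result(
          v, "chi-square", NA_real_, NA_character_, NA_real_,
          stats::setNames(
            rep("single observed category", nlevels(groups)),
            levels(groups)
          )
        )
      } else {
        chi_square_counts(tab, variable = v)
      }
    }
  })
  out <- do.call(rbind, rows)
  fss_means <- if ("fss_score" %in% names(cohort)) {
    tapply(cohort$fss_score, groups, mean)
  } else {
    NULL
  }
  phq_means <- if ("phq9_score" %in% names(cohort)) {
    tapply(cohort$phq9_score, groups, mean)
  } else {
    NULL
  }
  structure(out,
    class = c("profile_report", "data.frame"),
    cluster_labels = if (!is.null(fss_means)) {
      label_clusters(fss_means, phq_means)
    } else {
      NULL
    },
    fss_means = fss_means, n = nrow(cohort)
  )
}

#' @export
print.profile_report <- function(x, ...) {
  n <- attr(x, "n")
  if (!is.null(n)) cat(sprintf("Cluster profile (n = %d)\n", n))
  labs <- attr(x, "cluster_labels")
  if (!is.null(labs)) {
    for (i in seq_along(labs)) {
      cat(sprintf("  cluster %s: %s\n", names(labs)[i], labs[i]))
    }
  }
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Semantic cluster labels ordered by fatigue severity
#'
#' For three clusters, the canonical phenotype names (low / moderate / high
#' fatigue with correspondingly minimal / moderate / elevated psychological
#' and sleep-related symptoms); for two, lower/higher fatigue; otherwise
#' generic fatigue-rank labels. Ordering is by ascending mean FSS, ties by
#' ascending mean PHQ-9.
#'
#' @param fss_means Named vector of per-cluster mean FSS scores.
#' @param phq9_means Optional named vector of mean PHQ-9 scores
#'   (tie-break).
#' @return Named character vector of labels, one per cluster, in the input
#'   order of `fss_means`.
#' @export
label_clusters <- function(fss_means, phq9_means = NULL) {
  k <- length(fss_means)
  if (is.null(phq9_means)) phq9_means <- rep(0, k)
  ord <- order(fss_means, phq9_means)
  label_set <- if (k == 3) {
    c(
      "low fatigue with minimal psychological and sleep-related symptoms",
      "moderate fatigue with moderate psychological and sleep-related symptoms",
      "high fatigue with elevated psychological and sleep-related symptoms"
    )
  } else if (k == 2) {
    c("lower fatigue", "higher fatigue")
  } else {
    sprintf("fatigue rank %d of %d", seq_len(k), k)
  }
  out <- character(k)
  out[ord] <- label_set
  names(out) <- names(fss_means)
  out
}
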