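#' Association analysis configuration
#'
#' @param variables Variables entering the Spearman matrix.
#' @param alpha FDR level for the Benjamini-Hochberg correction.
#' @param control Covariates controlled for in the partial correlations.
#' @param fss_cutoff Clinical fatigue cut-off for the stratified split.
#' @param tertile_basis Variable whose upper tertile defines the stratum.
#' @return An object of class `assoc_config`.
#' @export
assoc_config <- function(variables = c(
                           "age", "years_dx", "bmi", "fss_score",
                           "phq9_score", "isi_score"
                         ),
                         alpha = 0.05, control = "age",
                         fss_cutoff = 4.67, tertile_basis = "age") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!all(control %in% variables)) {
    stop("control variables must be a subset of `variables`")
  }
  structure(
    list(
      variables = variables, alpha = alpha, control = control,
      fss_cutoff = fss_cutoff, tertile_basis = tertile_basis
    ),
    class = "assoc_config"
  )
}

# mid-rank transform of each column
rank_matrix <- function(x) apply(as.matrix(x), 2, rank, ties.method = "average")

# two-sided p from the t approximation for a (partial) correlation
corr_t_pvalue <- function(rho, df) {
  rho <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tstat <- rho * sqrt(df / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df)
}

#' Spearman rank-correlation matrix
#'
#' Tie-corrected Spearman correlations (Pearson on mid-ranks) for every
#' pair of the requested variables, with two-sided p-values from the t
#' approximation on n - 2 degrees of freedom.
#'
#' @param cohort Data frame with the variables as numeric columns.
#' @param variables Column names (default: the six association variables).
#' @return A list with matrices `rho` and `p` (unit diagonal; diagonal p
#'   set to `NA`) and the sample size `n`.
#' @export
spearman_matrix <- function(cohort,
                            variables = assoc_config()$variables) {
  assert_cols(cohort, variables)
  x <- as.matrix(cohort[variables])
  if (nrow(x) < 4) stop("need at least 4 complete observations")
  if (any(!is.finite(x))) stop("variables must be complete and finite")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop(
      "Spearman correlation undefined for constant variable: ",
      variables[which(sds == 0)[1L]]
    )
  }
  rho <- stats::cor(rank_matrix(x))
  p <- corr_t_pvalue(rho, nrow(x) - 2)
  diag(rho) <- 1
  diag(p) <- NA_real_
  list(rho = rho, p = p, n = nrow(x))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up procedure: the adjusted p-value of the i-th smallest p is
#' `min over j >= i of (m * p_(j) / j)`, capped at 1; a hypothesis is
#' rejected when its adjusted p is at most `alpha`.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return A list with `adjusted` (same order as input) and `reject`
#'   (logical).
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(p, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all variables (mid-ranks) and applies the Pearson
#' partial-correlation formula in its inverse-correlation-matrix form,
#' which equals the correlation of the residuals from regressing the ranks
#' of `x` and `y` on the ranks of the controls. Two-sided p from the t
#' approximation with `n - 2 - |z|` degrees of freedom.
#'
#' @param x,y Numeric vectors.
#' @param z Control variable(s): vector, matrix or data frame.
#' @return A list with `rho`, `p`, `n`, `df`.
#' @export
partial_spearman <- function(x, y, z) {
  z <- as.matrix(z)
  n <- length(x)
  if (length(y) != n || nrow(z) != n) stop("x, y, z must have equal length")
  if (n < 5) stop("need at least 5 complete observations")
  r <- rank_matrix(cbind(x = x, y = y, z))
  cm <- stats::cor(r)
  pm <- tryCatch(solve(cm), error = function(e) {
    stop("rank correlation matrix is singular (collinear controls?)")
  })
  rho <- -pm[1, 2] / sqrt(pm[1, 1] * pm[2, 2])
  df <- n - 2 - ncol(z)
  list(rho = rho, p = corr_t_pvalue(rho, df), n = n, df = df)
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney U with mid-rank tie handling. `U` counts the
#' pairs where the first group exceeds the second (ties count 1/2), so
#' `U + U' = n1 * n2`. The p-value is exact when both groups have at most
#' `exact_limit` observations and the data are tie-free; otherwise the
#' tie-corrected normal approximation is used.
#'
#' @param x,y Numeric samples (first and second group).
#' @param exact_limit Largest per-group size for the exact null
#'   distribution (default 20).
#' @return A list with `U`, `p`, `method`, group sizes and group
#'   mean +/- sd summaries.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 20) {
  n1 <- length(x)
  n2 <- length(y)
  if (!n1 || !n2) stop("both groups must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- n1 <= exact_limit && n2 <= exact_limit && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE)
  )
  list(
    U = unname(wt$statistic), p = wt$p.value,
    method = if (use_exact) "exact" else "normal approximation (tie-corrected)",
    n1 = n1, n2 = n2,
    mean_sd_1 = c(mean = mean(x), sd = stats::sd(x)),
    mean_sd_2 = c(mean = mean(y), sd = stats::sd(y))
  )
}

#' Upper-age-tertile fatigue stratification
#'
#' Participants at or above the empirical 2/3 quantile of the tertile
#' basis (linear-interpolation, type-7 quantile) are split into low- and
#' high-fatigue groups at the FSS clinical cut-off and compared on PHQ-9,
#' ISI, BMI and years since diagnosis with two-sided Mann-Whitney U tests.
#'
#' @param cohort Scored cohort data frame.
#' @param config An [assoc_config()].
#' @param compare_vars Variables compared between fatigue groups.
#' @return An object of class `stratified_comparison`: list with
#'   `threshold`, `rule`, `n_upper`, `group_sizes`, and `table` (one row
#'   per variable: U, p, per-group mean +/- sd). When either fatigue group
#'   is empty the table holds descriptives only and a warning is issued.
#' @export
tertile_stratified_comparison <- function(cohort, config = assoc_config(),
                                          compare_vars = c(
                                            "phq9_score", "isi_score",
                                            "bmi", "years_dx"
                                          )) {
  assert_cols(cohort, c(config$tertile_basis, "fss_score", compare_vars))
  basis <- cohort[[config$tertile_basis]]
  threshold <- stats::quantile(basis, 2 / 3, type = 7, names = FALSE)
  upper <- cohort[basis >= threshold, , drop = FALSE]
  if (nrow(upper) < 6) stop("fewer than 6 participants in the upper tertile")
  high <- upper$fss_score >= config$fss_cutoff
  sizes <- c(high = sum(high), low = sum(!high))
  empty <- any(sizes == 0)
  if (empty) {
    warning("one fatigue group is empty: reporting descriptives only")
  }
  rows <- lapply(compare_vars, function(v) {
    hx <- upper[[v]][high]
    lx <- upper[[v]][!high]
    if (empty) {
      all_v <- upper[[v]]
      data.frame(
        variable = v, U = NA_real_, p_value = NA_real_, method = "none",
        high_mean = if (sizes["high"]) mean(hx) else NA_real_,
        high_sd = if (sizes["high"] > 1) stats::sd(hx) else NA_real_,
        low_mean = if (sizes["low"]) mean(lx) else NA_real_,
        low_sd = if (sizes["low"] > 1) stats::sd(lx) else NA_real_,
        stringsAsFactors = FALSE
      )
    } else {
      mw <- mann_whitney_u(hx, lx)
      data.frame(
        variable = v, U = mw$U, p_value = mw$p, method = mw$method,
        high_mean = mw$mean_sd_1["mean"], high_sd = mw$mean_sd_1["sd"],
        low_mean = mw$mean_sd_2["mean"], low_sd = mw$mean_sd_2["sd"],
        stringsAsFactors = FALSE
      )
    }
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(
    list(
      threshold = threshold,
      rule = sprintf(
        "%s >= empirical 2/3 quantile (type-7 linear interpolation)",
        config$tertile_basis
      ),
      n_upper = nrow(upper), group_sizes = sizes, table = tab
    ),
    class = "stratified_comparison"
  )
}

#' @export
print.stratified_comparison <- function(x, ...) {
  cat(sprintf(
    "Upper tertile (%s, threshold %.2f): %d participants (%d high- / %d low-fatigue)\n",
    x$rule, x$threshold, x$n_upper, x$group_sizes["high"],
    x$group_sizes["low"]
  ))
  print.data.frame(x$table, row.names = FALSE)
  invisible(x)
}

#' Full association battery
#'
#' Spearman matrix over the configured variables with BH-FDR control on the
#' unique off-diagonal pairs, partial Spearman correlations of fatigue with
#' depressive symptoms and insomnia controlling for the configured
#' covariates (raw p, as is conventional for these follow-up analyses), and
#' the upper-tertile stratified Mann-Whitney comparisons.
#'
#' @param cohort Scored cohort data frame.
#' @param config An [assoc_config()].
#' @return An object of class `correlation_report`: list with `rho`, `p`,
#'   `adjusted_p`, `reject` (matrices), `pairs` (tidy per-pair table),
#'   `partial` (data frame), `stratified` (a `stratified_comparison`),
#'   `n`, `alpha`.
#' @export
associations <- function(cohort, config = assoc_config()) {
  sm <- spearman_matrix(cohort, config$variables)
  vars <- config$variables
  m <- length(vars)
  ij <- which(upper.tri(sm$rho), arr.ind = TRUE)
  raw <- sm$p[upper.tri(sm$p)]
  bh <- bh_adjust(raw, config$alpha)
  adjusted_p <- matrix(NA_real_, m, m, dimnames = dimnames(sm$p))
  reject <- matrix(NA, m, m, dimnames = dimnames(sm$p))
  adjusted_p[upper.tri(adjusted_p)] <- bh$adjusted
  adjusted_p[lower.tri(adjusted_p)] <- t(adjusted_p)[lower.tri(adjusted_p)]
  reject[upper.tri(reject)] <- bh$reject
  reject[lower.tri(reject)] <- t(reject)[lower.tri(reject)]
  pairs <- data.frame(
    var1 = vars[ij[, 1]], var2 = vars[ij[, 2]],
    rho = sm$rho[ij], p = raw, p_adjusted = bh$adjusted,
    reject = bh$reject, stringsAsFactors = FALSE
  )
  zc <- as.matrix(cohort[config$control])
  partial_for <- function(v) {
    ps <- partial_spearman(cohort$fss_score, cohort[[v]], zc)
    data.frame(
      pair = paste0("fss_score~", v),
      control = paste(config$control, collapse = "+"),
      rho = ps$rho, p = ps$p, stringsAsFactors = FALSE
    )
  }
  partial <- do.call(rbind, lapply(
    intersect(c("phq9_score", "isi_score"), vars), partial_for
  ))
  structure(
    list(
      rho = sm$rho, p = sm$p, adjusted_p = adjusted_p, reject = reject,
      pairs = pairs, partial = partial,
      stratified = tertile_stratified_comparison(cohort, config),
      n = sm$n, alpha = config$alpha
    ),
    class = "correlation_report"
  )
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf(
    "Spearman association battery (n = %d, BH-FDR alpha = %g)\n", x$n,
    x$alpha
  ))
  print.data.frame(x$pairs, row.names = FALSE, digits = 3)
  cat("Partial correlations (controlling for",
    unique(x$partial$control), "):\n")
  print.data.frame(x$partial, row.names = FALSE, digits = 3)
  invisible(x)
}
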