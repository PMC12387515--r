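#' Per-cluster generating parameters for a synthetic cohort
#'
#' Describes one latent cluster of the synthetic cohort: its expected share
#' of the sample, Gaussian (mean, sd) parameters for age and the three
#' instrument scores, quartile parameters (median, q1, q3) for the
#' right-skewed BMI and disease-duration variables, and the male fraction.
#'
#' @param label Cluster identifier (integer or character).
#' @param weight Expected fraction of the cohort in this cluster.
#' @param age `c(mean, sd)` in years.
#' @param bmi `c(median, q1, q3)` in kg/m^2.
#' @param years_dx `c(median, q1, q3)` years since diagnosis.
#' @param phq9,isi,fss `c(mean, sd)` on the instrument scale.
#' @param male_frac Proportion of males in `[0, 1]`.
#' @return An object of class `cluster_spec`.
#' @seealso [default_cluster_specs()] for the three-cluster defaults.
#' @export
cluster_spec <- function(label, weight, age, bmi, years_dx, phq9, isi, fss,
                         male_frac) {
  chk_ms <- function(x, what) {
    if (length(x) != 2L || !all(is.finite(x)) || x[2] <= 0) {
      stop(what, " must be c(mean, sd) with sd > 0")
    }
  }
  chk_q <- function(x, what) {
    if (length(x) != 3L || !all(is.finite(x)) || x[2] <= 0 ||
      !(x[2] < x[1] && x[1] < x[3])) {
      stop(what, " must be c(median, q1, q3) with 0 < q1 < median < q3")
    }
  }
  chk_ms(age, "age")
  chk_ms(phq9, "phq9")
  chk_ms(isi, "isi")
  chk_ms(fss, "fss")
  chk_q(bmi, "bmi")
  chk_q(years_dx, "years_dx")
  if (weight < 0 || male_frac < 0 || male_frac > 1) {
    stop("weight must be >= 0 and male_frac in [0, 1]")
  }
  structure(
    list(
      label = label, weight = weight, age = age, bmi = bmi,
      years_dx = years_dx, phq9 = phq9, isi = isi, fss = fss,
      male_frac = male_frac
    ),
    class = "cluster_spec"
  )
}

#' Default three-cluster specification
#'
#' The default latent structure used throughout the package: three fatigue
#' phenotypes (low / moderate / high) with cluster weights 49:32:46,
#' increasing age, BMI, disease duration, depressive symptoms, insomnia and
#' fatigue severity across clusters, and no sex effect beyond the per-cluster
#' male fraction.
#'
#' @return A list of three [cluster_spec()] objects.
#' @export
default_cluster_specs <- function() {
  list(
    cluster_spec(1L, 49 / 127,
      age = c(22.6, 3.1), bmi = c(20.0, 18.4, 21.4),
      years_dx = c(8.6, 6.6, 10.0), phq9 = c(3.5, 2.6),
      isi = c(4.3, 3.7), fss = c(2.7, 0.8), male_frac = 0.408
    ),
    cluster_spec(2L, 32 / 127,
      age = c(36.4, 5.9), bmi = c(21.8, 19.5, 23.6),
      years_dx = c(12.1, 9.7, 15.0), phq9 = c(5.8, 3.7),
      isi = c(6.7, 4.5), fss = c(3.5, 1.1), male_frac = 0.531
    ),
    cluster_spec(3L, 46 / 127,
      age = c(53.5, 6.1), bmi = c(23.9, 22.5, 25.6),
      years_dx = c(15.6, 13.7, 19.0), phq9 = c(7.2, 3.6),
      isi = c(8.8, 4.8), fss = c(4.9, 1.0), male_frac = 0.522
    )
  )
}

#' Default within-cluster Spearman correlation targets
#'
#' Targets for the Gaussian copula over the generated variables, in the
#' order `age, bmi, years_dx, fss, phq9, isi`: fatigue correlates with
#' depressive symptoms (0.62) and insomnia (0.41), and age with BMI (0.51);
#' all other pairs are independent within cluster.
#'
#' @return A symmetric 6x6 matrix with unit diagonal.
#' @export
default_rank_corr_targets <- function() {
  v <- c("age", "bmi", "years_dx", "fss", "phq9", "isi")
  m <- diag(6)
  dimnames(m) <- list(v, v)
  m["fss", "phq9"] <- m["phq9", "fss"] <- 0.62
  m["fss", "isi"] <- m["isi", "fss"] <- 0.41
  m["age", "bmi"] <- m["bmi", "age"] <- 0.51
  m
}

#' Synthetic cohort configuration
#'
#' @param n Cohort size (default 127).
#' @param cluster_specs List of [cluster_spec()]; weights are normalised.
#' @param rank_corr_targets Symmetric within-cluster Spearman target matrix
#'   over `age, bmi, years_dx, fss, phq9, isi`
#'   (default [default_rank_corr_targets()]).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param item_level If `TRUE`, item-level instrument responses consistent
#'   with each total are emitted as well.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 127, cluster_specs = default_cluster_specs(),
                          rank_corr_targets = default_rank_corr_targets(),
                          seed = 1L, item_level = FALSE) {
  assert_count(n, "n", min = length(cluster_specs))
  if (!length(cluster_specs) ||
    !all(vapply(cluster_specs, inherits, logical(1), "cluster_spec"))) {
    stop("cluster_specs must be a non-empty list of cluster_spec objects")
  }
  validate_rank_targets(rank_corr_targets)
  structure(
    list(
      n = as.integer(n), cluster_specs = cluster_specs,
      rank_corr_targets = rank_corr_targets, seed = as.integer(seed),
      item_level = isTRUE(item_level)
    ),
    class = "cohort_config"
  )
}

validate_rank_targets <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
    max(abs(m - t(m))) > 1e-12 || any(abs(diag(m) - 1) > 1e-12) ||
    any(abs(m) > 1)) {
    stop("rank_corr_targets must be a symmetric matrix with unit diagonal ",
      "and entries in [-1, 1]")
  }
  invisible(m)
}

#' Fit a log-normal distribution to a reported median and quartiles
#'
#' Converts a published `median (q1-q3)` summary into log-normal parameters
#' by quantile matching: `mu = log(median)` and
#' `sigma = log(q3/q1) / (2 * z_{0.75})` with `z_{0.75} = qnorm(0.75)`.
#' The fitted distribution reproduces the median exactly and the quartile
#' ratio exactly; it matches both quartiles exactly only when the printed
#' quartiles are themselves log-symmetric around the median.
#'
#' @param median,q1,q3 Reported median and quartiles, `0 < q1 < median < q3`.
#' @return `c(mu = ..., sigma = ...)` of the log-normal.
#' @examples
#' fit_quartile_lognormal(21.33, 19.11, 23.41)
#' @export
fit_quartile_lognormal <- function(median, q1, q3) {
  if (any(!is.finite(c(median, q1, q3))) || q1 <= 0 ||
    !(q1 < median && median < q3)) {
    stop("need 0 < q1 < median < q3")
  }
  c(mu = log(median), sigma = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

#' Sample uniforms with a target Spearman correlation structure
#'
#' Draws `n` rows whose margins are uniform on (0, 1) and whose pairwise
#' Spearman correlations converge to `rank_corr_targets` as `n` grows, via a
#' Gaussian copula. The latent Pearson correlation used for the Gaussian
#' layer is `r = 2 * sin(pi * rho / 6)`, which is exact for this copula.
#'
#' @param rank_corr_targets Symmetric Spearman target matrix, unit diagonal.
#' @param n Number of rows.
#' @param seed Optional integer seed (local RNG stream).
#' @param repair If `TRUE` and the converted latent matrix is not positive
#'   definite, replace it by the nearest positive-definite matrix
#'   (`Matrix::nearPD`) instead of failing.
#' @return An `n x d` matrix of uniforms.
#' @export
gaussian_copula_sample <- function(rank_corr_targets, n, seed = NULL,
                                   repair = FALSE) {
  validate_rank_targets(rank_corr_targets)
  assert_count(n, "n", min = 1)
  r <- 2 * sin(pi * rank_corr_targets / 6)
  diag(r) <- 1
  eg <- eigen(r, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    if (!repair) {
      stop("converted latent correlation matrix is not positive definite; ",
        "rerun with repair = TRUE to use the nearest positive-definite ",
        "matrix")
    }
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("repair = TRUE requires the Matrix package")
    }
    r <- as.matrix(Matrix::nearPD(r, corr = TRUE)$mat)
    eg <- eigen(r, symmetric = TRUE)
  }
  # eigen factor rather than Cholesky so that semi-definite targets
  # (comonotone pairs, |rho| = 1) are handled exactly
  fac <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), ncol(r)) %*%
    t(eg$vectors)
  d <- ncol(r)
  draw <- function() {
    z <- matrix(stats::rnorm(n * d), n, d) %*% fac
    stats::pnorm(z)
  }
  u <- if (is.null(seed)) draw() else with_seed(seed, draw())
  colnames(u) <- colnames(rank_corr_targets)
  u
}

# ---- moment-matched truncated normal -------------------------------------

# mean/sd of a normal(mu, sigma) truncated to [a, b]
trunc_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  fa <- stats::dnorm(al)
  fb <- stats::dnorm(be)
  m <- mu + sigma * (fa - fb) / z
  v <- sigma^2 * (1 + (al * fa - be * fb) / z - ((fa - fb) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# latent (mu, sigma) such that the [a, b]-truncated normal has the target
# mean and sd; identity when truncation mass is negligible
match_truncnorm <- function(mean, sd, a, b) {
  tail_mass <- stats::pnorm(a, mean, sd) + stats::pnorm(b, mean, sd,
    lower.tail = FALSE
  )
  if (tail_mass < 1e-10) {
    return(c(mu = mean, sigma = sd))
  }
  obj <- function(par) {
    mom <- trunc_moments(par[1], exp(par[2]), a, b)
    (mom["mean"] - mean)^2 + (mom["sd"] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 2000)
  )
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# quantile function of the truncated normal, applied to uniforms
qtruncnorm_ <- function(u, mu, sigma, a, b) {
  pa <- stats::pnorm(a, mu, sigma)
  pb <- stats::pnorm(b, mu, sigma)
  q <- stats::qnorm(pa + u * (pb - pa), mu, sigma)
  pmin(pmax(q, a), b) # guard numerical spill at u ~ 0/1
}

#' Generate a synthetic cohort with latent cluster structure
#'
#' Cluster sizes follow largest-remainder apportionment of the spec weights
#' (the defaults give 49/32/46 at n = 127). Within each cluster, dependence
#' across `age, bmi, years_dx, fss, phq9, isi` is induced by a Gaussian
#' copula hitting the configured Spearman targets; margins are Gaussian for
#' age, log-normal (quartile-matched) for BMI and years since diagnosis, and
#' moment-matched truncated normals on the instrument scales for FSS
#' (continuous on `[1, 7]`), PHQ-9 (integer 0-27) and ISI (integer 0-28), so
#' that the realised within-cluster means and SDs reproduce the configured
#' values despite the bounded scales. Sex is Bernoulli(male_frac),
#' independent of all scores within cluster. Deterministic given the seed.
#'
#' @param config A [cohort_config()].
#' @return A data frame with columns `id`, `true_cluster`, `age`, `sex`,
#'   `years_dx`, `bmi`, `fss_score`, `phq9_score`, `isi_score` (plus
#'   item-level columns when `item_level = TRUE`), carrying the cluster
#'   sizes as attribute `cluster_sizes`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 127, seed = 42))
#' table(cohort$true_cluster)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- config$cluster_specs
  weights <- vapply(specs, `[[`, numeric(1), "weight")
  sizes <- largest_remainder(config$n, weights)
  if (any(sizes == 0) && config$n < length(specs)) {
    stop("n is smaller than the number of clusters")
  }
  pieces <- vector("list", length(specs))
  for (ci in seq_along(specs)) {
    sp <- specs[[ci]]
    nc <- sizes[ci]
    if (nc == 0) next
    u <- gaussian_copula_sample(config$rank_corr_targets, nc,
      seed = substream_seed(config$seed, "copula", ci)
    )
    bmi_par <- fit_quartile_lognormal(sp$bmi[1], sp$bmi[2], sp$bmi[3])
    ydx_par <- fit_quartile_lognormal(
      sp$years_dx[1], sp$years_dx[2], sp$years_dx[3]
    )
    fss_par <- match_truncnorm(sp$fss[1], sp$fss[2], 1, 7)
    phq_par <- match_truncnorm(sp$phq9[1], sp$phq9[2], 0, 27)
    isi_par <- match_truncnorm(sp$isi[1], sp$isi[2], 0, 28)
    sex <- with_seed(
      substream_seed(config$seed, "sex", ci),
      ifelse(stats::runif(nc) < sp$male_frac, "male", "female")
    )
    pieces[[ci]] <- data.frame(
      true_cluster = rep(sp$label, nc),
      age = stats::qnorm(u[, "age"], sp$age[1], sp$age[2]),
      sex = sex,
      years_dx = stats::qlnorm(u[, "years_dx"], ydx_par[1], ydx_par[2]),
      bmi = stats::qlnorm(u[, "bmi"], bmi_par[1], bmi_par[2]),
      fss_score = qtruncnorm_(u[, "fss"], fss_par[1], fss_par[2], 1, 7),
      phq9_score = as.integer(round(
        qtruncnorm_(u[, "phq9"], phq_par[1], phq_par[2], 0, 27)
      )),
      isi_score = as.integer(round(
        qtruncnorm_(u[, "isi"], isi_par[1], isi_par[2], 0, 28)
      )),
      stringsAsFactors = FALSE
    )
  }
  cohort <- do.call(rbind, pieces)
  cohort <- cbind(
    id = sprintf("P%04d", seq_len(nrow(cohort))), cohort,
    stringsAsFactors = FALSE
  )
  rownames(cohort) <- NULL
  if (config$item_level) {
    cohort <- add_instrument_items(cohort,
      seed = substream_seed(config$seed, "items")
    )
  }
  attr(cohort, "cluster_sizes") <- stats::setNames(
    sizes, vapply(specs, function(s) as.character(s$label), character(1))
  )
  cohort
}

# ---- item-level emission -------------------------------------------------

# number of ways to write total t as k items each in 0..h (DP, exact doubles
# for the scales involved)
compositions_count <- function(t, k, h) {
  if (t < 0 || t > k * h) {
    return(0)
  }
  counts <- c(1, rep(0, k * h)) # counts[t+1] = ways with 0 items
  for (i in seq_len(k)) {
    new <- rep(0, k * h + 1)
    for (tt in 0:(i * h)) {
      lo <- max(0, tt - h)
      new[tt + 1] <- sum(counts[(lo + 1):(tt + 1)])
    }
    counts <- new
  }
  counts[t + 1]
}

#' Emit item-level responses consistent with a total score
#'
#' Draws one composition of an instrument total into valid item responses,
#' uniformly at random over all compositions (sequential conditional
#' sampling with exact composition counts).
#'
#' @param total Integer total (for FSS, the rounded `9 * score`).
#' @param n_items Number of items.
#' @param lo,hi Item response range.
#' @param seed Optional integer seed.
#' @return Integer vector of `n_items` responses in `lo..hi` summing to
#'   `total`.
#' @examples
#' emit_items(27, 9, 0, 3) # nine 3s: unique composition
#' @export
emit_items <- function(total, n_items, lo, hi, seed = NULL) {
  assert_count(n_items, "n_items")
  if (!is.finite(total) || total != round(total) ||
    total < n_items * lo || total > n_items * hi) {
    stop(sprintf(
      "total %s impossible for %d items in %d..%d", format(total), n_items,
      lo, hi
    ))
  }
  h <- hi - lo
  t_rem <- as.integer(total) - n_items * lo
  draw <- function() {
    items <- integer(n_items)
    for (i in seq_len(n_items)) {
      k_rest <- n_items - i
      vals <- max(0, t_rem - k_rest * h):min(h, t_rem)
      w <- vapply(vals, function(v) {
        compositions_count(t_rem - v, k_rest, h)
      }, numeric(1))
      v <- if (length(vals) == 1L) vals else sample(vals, 1, prob = w)
      items[i] <- v
      t_rem <- t_rem - v
    }
    as.integer(items + lo)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Add item-level instrument columns to a cohort
#'
#' For every participant, emits FSS, PHQ-9 and ISI item responses consistent
#' with the stored totals (FSS items reproduce the stored score to within
#' the 1/18 resolution of a 9-item mean).
#'
#' @param cohort Cohort data frame with `fss_score`, `phq9_score`,
#'   `isi_score`.
#' @param seed Integer seed.
#' @return The cohort with `fss_1..9`, `phq9_1..9`, `isi_1..7` appended.
#' @export
add_instrument_items <- function(cohort, seed = 1L) {
  assert_cols(cohort, c("fss_score", "phq9_score", "isi_score"))
  n <- nrow(cohort)
  emit_all <- function(totals, k, lo, hi, prefix, stream) {
    m <- t(vapply(seq_len(n), function(i) {
      emit_items(totals[i], k, lo, hi,
        seed = substream_seed(seed, stream, i)
      )
    }, integer(k)))
    colnames(m) <- paste0(prefix, "_", seq_len(k))
    m
  }
  fss_tot <- pmin(pmax(round(cohort$fss_score * 9), 9L), 63L)
  cbind(
    cohort,
    emit_all(fss_tot, 9L, 1L, 7L, "fss", "fss"),
    emit_all(cohort$phq9_score, 9L, 0L, 3L, "phq9", "phq9"),
    emit_all(cohort$isi_score, 7L, 0L, 4L, "isi", "isi"),
    stringsAsFactors = FALSE
  )
}

#' Write a cohort and its truth labels as delimited text
#'
#' The cohort goes to `path` as UTF-8 CSV with a header row and `.` decimal
#' separator; when ground-truth labels are present they are additionally
#' written to `truth_path` as an `id,true_cluster` table.
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @param truth_path Optional path for the truth file (default:
#'   `<path>_truth.csv` next to `path`); `NA` suppresses it.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  written <- path
  if (!is.null(truth_path) && is.na(truth_path)) truth_path <- NULL
  if (is.null(truth_path) && "true_cluster" %in% names(cohort)) {
    truth_path <- sub("\\.csv$", "_truth.csv", path)
  }
  if (!is.null(truth_path) && "true_cluster" %in% names(cohort)) {
    utils::write.csv(cohort[c("id", "true_cluster")], truth_path,
      row.names = FALSE, fileEncoding = "UTF-8"
    )
    written <- c(written, truth_path)
  }
  invisible(written)
}

#' Read a cohort generation config from a YAML file
#'
#' Expected keys: `n`, `seed`, `item_level`, optional `clusters` (a list of
#' per-cluster mappings with the [cluster_spec()] fields) and
#' `rank_corr_targets` (a list of `[var1, var2, rho]` triples over
#' `age, bmi, years_dx, fss, phq9, isi`).
#'
#' @param path YAML file path.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `n:` key as the boolean "no"; accept both
  if (is.null(y[["n"]]) && "FALSE" %in% names(y)) {
    names(y)[names(y) == "FALSE"] <- "n"
  }
  specs <- if (is.null(y$clusters)) {
    default_cluster_specs()
  } else {
    lapply(y$clusters, function(cl) {
      cluster_spec(
        label = cl$label, weight = cl$weight,
        age = as.numeric(cl$age), bmi = as.numeric(cl$bmi),
        years_dx = as.numeric(cl$years_dx), phq9 = as.numeric(cl$phq9),
        isi = as.numeric(cl$isi), fss = as.numeric(cl$fss),
        male_frac = cl$male_frac
      )
    })
  }
  targets <- default_rank_corr_targets()
  if (!is.null(y$rank_corr_targets)) {
    targets[, ] <- diag(nrow(targets))
    for (tr in y$rank_corr_targets) {
      targets[tr[[1]], tr[[2]]] <- as.numeric(tr[[3]])
      targets[tr[[2]], tr[[1]]] <- as.numeric(tr[[3]])
    }
  }
  cohort_config(
    n = y$n %||% 127, cluster_specs = specs, rank_corr_targets = targets,
    seed = y$seed %||% 1L, item_level = isTRUE(y$item_level)
  )
}
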