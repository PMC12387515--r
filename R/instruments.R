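#' Clinical thresholds for the three self-report instruments
#'
#' Bundles the published interpretation rules: the FSS clinical cut-off
#' (item-mean score of at least 4.67 marks clinically significant fatigue),
#' the PHQ-9 severity bands (0-4 none, 5-9 minimal, 10-14 mild, 15-19
#' moderate, >= 20 severe) and the ISI severity bands (0-7 none, 8-14
#' subthreshold, 15-21 moderate, 22-28 severe). Every breakpoint is an
#' inclusive lower bound of the upper band.
#'
#' @param fss_clinical_cutoff FSS score (1-7 scale) at or above which fatigue
#'   is classified as clinically relevant. Default 4.67.
#' @param phq9_breaks,phq9_labels PHQ-9 band breakpoints (strictly increasing
#'   integers) and the band labels (one more label than breakpoints).
#' @param isi_breaks,isi_labels ISI band breakpoints and labels, same rules.
#' @return An object of class `instrument_thresholds`.
#' @export
instrument_thresholds <- function(
    fss_clinical_cutoff = 4.67,
    phq9_breaks = c(5L, 10L, 15L, 20L),
    phq9_labels = c(
      "no depressive symptoms", "minimal depression", "mild depression",
      "moderate depression", "severe depression"
    ),
    isi_breaks = c(8L, 15L, 22L),
    isi_labels = c(
      "no clinically significant insomnia", "subthreshold insomnia",
      "moderate clinical insomnia", "severe clinical insomnia"
    )) {
  check_bands <- function(breaks, labels, what) {
    if (any(diff(breaks) <= 0)) {
      stop(what, " breakpoints must be strictly increasing")
    }
    if (length(labels) != length(breaks) + 1L) {
      stop(what, " needs exactly one more label than breakpoints")
    }
  }
  check_bands(phq9_breaks, phq9_labels, "PHQ-9")
  check_bands(isi_breaks, isi_labels, "ISI")
  if (fss_clinical_cutoff < 1 || fss_clinical_cutoff > 7) {
    stop("FSS clinical cutoff must lie within the 1-7 scale")
  }
  structure(
    list(
      fss_clinical_cutoff = fss_clinical_cutoff,
      phq9_breaks = phq9_breaks, phq9_labels = phq9_labels,
      isi_breaks = isi_breaks, isi_labels = isi_labels
    ),
    class = "instrument_thresholds"
  )
}

#' @export
print.instrument_thresholds <- function(x, ...) {
  cat("Instrument thresholds\n")
  cat(sprintf("  FSS clinical cutoff: >= %.2f\n", x$fss_clinical_cutoff))
  cat("  PHQ-9 bands:", paste(x$phq9_labels, collapse = " | "), "\n")
  cat("  ISI bands:  ", paste(x$isi_labels, collapse = " | "), "\n")
  invisible(x)
}

# map a score to its band label; each breakpoint belongs to the upper band
band_label <- function(score, breaks, labels) {
  labels[findInterval(score, breaks) + 1L]
}

check_items <- function(items, n_items, lo, hi, instrument) {
  if (length(items) != n_items) {
    stop(sprintf(
      "%s requires exactly %d items, got %d", instrument, n_items,
      length(items)
    ))
  }
  bad <- which(!is.finite(items) | items != round(items) |
    items < lo | items > hi)
  if (length(bad)) {
    stop(sprintf(
      "%s item %d is invalid (must be an integer in %d..%d)",
      instrument, bad[1L], lo, hi
    ))
  }
  invisible(items)
}

new_scored <- function(instrument, score, category) {
  structure(
    list(instrument = instrument, score = score, category = category),
    class = "scored_instrument"
  )
}

#' @export
print.scored_instrument <- function(x, ...) {
  cat(sprintf("%s score %.3g: %s\n", x$instrument, x$score, x$category))
  invisible(x)
}

#' Score the Fatigue Severity Scale (FSS)
#'
#' The FSS has nine statements rated 1 (strongly disagree) to 7 (strongly
#' agree); the score is the item mean, and a score of at least 4.67 indicates
#' clinically significant fatigue. Either the nine items or a precomputed
#' score may be supplied; if both are given they must agree (to 1e-9) or the
#' record is rejected as inconsistent.
#'
#' @param items Nine integer ratings in 1..7, or `NULL`.
#' @param score Precomputed FSS score in `[1, 7]`, or `NULL`.
#' @param thresholds An [instrument_thresholds()] object.
#' @return A `scored_instrument` with fields `instrument`, `score`,
#'   `category` (`"clinically relevant fatigue"` or `"not clinically
#'   relevant"`).
#' @examples
#' score_fss(rep(4L, 9))$category
#' score_fss(score = 4.67)$category
#' @export
score_fss <- function(items = NULL, score = NULL,
                      thresholds = instrument_thresholds()) {
  if (is.null(items) && is.null(score)) {
    stop("FSS: supply items or a precomputed score")
  }
  if (!is.null(items)) {
    check_items(items, 9L, 1L, 7L, "FSS")
    m <- mean(items)
    if (!is.null(score) && abs(score - m) > 1e-9) {
      stop(sprintf(
        "FSS: supplied score %.6f disagrees with item mean %.6f", score, m
      ))
    }
    score <- m
  }
  if (!is.finite(score) || score < 1 || score > 7) {
    stop("FSS score must lie in [1, 7]")
  }
  cat_ <- if (score >= thresholds$fss_clinical_cutoff) {
    "clinically relevant fatigue"
  } else {
    "not clinically relevant"
  }
  new_scored("FSS", score, cat_)
}

#' Score the Patient Health Questionnaire-9 (PHQ-9)
#'
#' Nine items scored 0 (not at all) to 3 (nearly every day), summed to a
#' 0-27 total and banded by severity.
#'
#' @inheritParams score_fss
#' @param items Nine integer ratings in 0..3, or `NULL`.
#' @param score Precomputed integer total in 0..27, or `NULL`.
#' @return A `scored_instrument`; `category` is the PHQ-9 severity band.
#' @examples
#' score_phq9(rep(0L, 9))$category # "no depressive symptoms"
#' score_phq9(score = 10)$category # "mild depression"
#' @export
score_phq9 <- function(items = NULL, score = NULL,
                       thresholds = instrument_thresholds()) {
  score <- sum_score(items, score, 9L, 0L, 3L, "PHQ-9")
  new_scored(
    "PHQ9", score,
    band_label(score, thresholds$phq9_breaks, thresholds$phq9_labels)
  )
}

#' Score the Insomnia Severity Index (ISI)
#'
#' Seven items rated 0-4, summed to a 0-28 total and banded by severity.
#'
#' @inheritParams score_fss
#' @param items Seven integer ratings in 0..4, or `NULL`.
#' @param score Precomputed integer total in 0..28, or `NULL`.
#' @return A `scored_instrument`; `category` is the ISI severity band.
#' @examples
#' score_isi(score = 15)$category # "moderate clinical insomnia"
#' @export
score_isi <- function(items = NULL, score = NULL,
                      thresholds = instrument_thresholds()) {
  score <- sum_score(items, score, 7L, 0L, 4L, "ISI")
  new_scored(
    "ISI", score,
    band_label(score, thresholds$isi_breaks, thresholds$isi_labels)
  )
}

sum_score <- function(items, score, n_items, lo, hi, instrument) {
  if (is.null(items) && is.null(score)) {
    stop(instrument, ": supply items or a precomputed score")
  }
  if (!is.null(items)) {
    check_items(items, n_items, lo, hi, instrument)
    s <- sum(items)
    if (!is.null(score) && abs(score - s) > 1e-9) {
      stop(sprintf(
        "%s: supplied score %s disagrees with item sum %d", instrument,
        format(score), s
      ))
    }
    score <- s
  }
  if (!is.finite(score) || score != round(score) ||
    score < n_items * lo || score > n_items * hi) {
    stop(sprintf(
      "%s score must be an integer in %d..%d", instrument,
      n_items * lo, n_items * hi
    ))
  }
  as.integer(score)
}

#' Body mass index
#'
#' @param weight Weight in kilograms (> 0).
#' @param height Height in metres (> 0).
#' @return BMI in kg/m^2 (weight divided by height squared). Vectorised.
#' @examples
#' compute_bmi(80, 2.0) # 20
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("weight must be positive and finite")
  }
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("height must be positive and finite")
  }
  weight / height^2
}

#' Score all instruments across a cohort table
#'
#' Adds scored columns `fss_score`, `fss_clinical`, `phq9_score`,
#' `phq9_band`, `isi_score`, `isi_band` and `bmi` to a cohort data frame.
#' Item-level columns take precedence over total-score columns when both are
#' present (and must agree); BMI is computed from `weight`/`height` columns
#' when no `bmi` column exists. Missing items are not imputed: any
#' non-finite value aborts with the offending row.
#'
#' @param cohort A data frame, one row per participant.
#' @param thresholds An [instrument_thresholds()] object.
#' @param columns Naming scheme: a list with entries `fss_items`,
#'   `phq9_items`, `isi_items` (character vectors of item columns, or `NULL`
#'   to use `<prefix>_1 ...` when present), `fss_total`, `phq9_total`,
#'   `isi_total`, `weight`, `height`, `bmi`.
#' @return The cohort with scored columns appended (existing scored columns
#'   are recomputed).
#' @export
score_cohort <- function(cohort, thresholds = instrument_thresholds(),
                         columns = list()) {
  stopifnot(is.data.frame(cohort))
  cols <- utils::modifyList(
    list(
      fss_items = NULL, phq9_items = NULL, isi_items = NULL,
      fss_total = "fss_score", phq9_total = "phq9_score",
      isi_total = "isi_score",
      weight = "weight", height = "height", bmi = "bmi"
    ),
    columns
  )
  find_items <- function(given, prefix, k) {
    if (!is.null(given)) {
      return(given)
    }
    cand <- paste0(prefix, "_", seq_len(k))
    if (all(cand %in% names(cohort))) cand else NULL
  }
  score_rows <- function(item_cols, total_col, fun) {
    items <- if (!is.null(item_cols)) {
      assert_cols(cohort, item_cols)
      as.matrix(cohort[item_cols])
    } else {
      NULL
    }
    totals <- if (total_col %in% names(cohort)) cohort[[total_col]] else NULL
    if (is.null(items) && is.null(totals)) {
      stop(
        "cohort has neither item columns nor a total column for ",
        total_col
      )
    }
    lapply(seq_len(nrow(cohort)), function(i) {
      tryCatch(
        fun(
          items = if (!is.null(items)) as.vector(items[i, ]) else NULL,
          score = if (!is.null(totals)) totals[i] else NULL,
          thresholds = thresholds
        ),
        error = function(e) stop(sprintf("row %d: %s", i, conditionMessage(e)),
          call. = FALSE
        )
      )
    })
  }
  fss <- score_rows(find_items(cols$fss_items, "fss", 9L), cols$fss_total, score_fss)
  phq <- score_rows(find_items(cols$phq9_items, "phq9", 9L), cols$phq9_total, score_phq9)
  isi <- score_rows(find_items(cols$isi_items, "isi", 7L), cols$isi_total, score_isi)
  cohort$fss_score <- vapply(fss, `[[`, numeric(1), "score")
  cohort$fss_clinical <- vapply(fss, `[[`, character(1), "category") ==
    "clinically relevant fatigue"
  cohort$phq9_score <- vapply(phq, `[[`, numeric(1), "score")
  cohort$phq9_band <- vapply(phq, `[[`, character(1), "category")
  cohort$isi_score <- vapply(isi, `[[`, numeric(1), "score")
  cohort$isi_band <- vapply(isi, `[[`, character(1), "category")
  if (!(cols$bmi %in% names(cohort))) {
    assert_cols(cohort, c(cols$weight, cols$height))
    cohort$bmi <- compute_bmi(cohort[[cols$weight]], cohort[[cols$height]])
  }
  cohort
}
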