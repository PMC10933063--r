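# Novelty / scalability metrics on yearly document-frequency trajectories,
# quintile rank scores, stoplist exclusion, and category assignment.
#
# Novelty is read from average frequency and relative volatility; scalability
# from the average acceleration of a term's appearance. Each metric is
# converted to a 1-5 quintile score over the candidate pool, and categories
# follow fixed score rules:
#   hazardous   all three scores >= 4
#   noteworthy  frequency <= 2, acceleration >= 3, volatility >= 3
#   diffusion   frequency >= 4, acceleration <= 2 (volatility free)

#' Average yearly document frequency
#'
#' Mean frequency over all study years; years without an observation count as
#' zero (pass a zero-filled series).
#'
#' @param freq Numeric vector of yearly document frequencies, one entry per
#'   study year, zero-filled.
#' @param n_years Number of study years (defaults to `length(freq)`).
#' @return Mean frequency.
#' @export
average_frequency <- function(freq, n_years = length(freq)) {
  if (!is_count(n_years, min = 1L)) rlang::abort("`n_years` must be >= 1.")
  sum(freq) / n_years
}

#' Average acceleration of a term's appearance
#'
#' Yearly increments of document frequency are accumulated from the first
#' study year through the year of the term's last appearance (last non-zero
#' frequency); the metric is their mean. With first differences this is a
#' velocity-style growth rate: negative for declining terms. The
#' `"second_difference"` variant takes one further difference before
#' averaging.
#'
#' Terms whose trajectory spans fewer than two years up to the last
#' appearance (including all-zero trajectories) get 0 with attribute
#' `undefined = TRUE`.
#'
#' @inheritParams average_frequency
#' @param variant `"first_difference"` (default) or `"second_difference"`.
#' @return Mean increment (may be negative).
#' @export
average_acceleration <- function(freq,
                                 variant = c("first_difference",
                                             "second_difference")) {
  variant <- match.arg(variant)
  nz <- which(freq != 0)
  if (length(nz) == 0L) return(structure(0, undefined = TRUE))
  last <- nz[length(nz)]
  min_span <- if (variant == "first_difference") 2L else 3L
  if (last < min_span) return(structure(0, undefined = TRUE))
  inc <- diff(freq[seq_len(last)])
  if (variant == "second_difference") inc <- diff(inc)
  mean(inc)
}

#' Standard deviation of a yearly trajectory
#'
#' @inheritParams average_frequency
#' @param variant `"population"` (divide by n, default) or `"sample"`.
#' @return Non-negative SD.
#' @export
trajectory_sd <- function(freq, variant = c("population", "sample")) {
  variant <- match.arg(variant)
  if (variant == "population") sd_pop(freq) else stats::sd(freq)
}

#' Relative volatility of a term
#'
#' Ratio of the term's trajectory SD to the mean trajectory SD over a pool of
#' terms (normally the candidate keywords), which discounts the overall
#' growth of the vocabulary over time.
#'
#' @inheritParams average_frequency
#' @param all_sds Numeric vector of trajectory SDs for every pooled term.
#' @param sd_variant Passed to [trajectory_sd()].
#' @return Non-negative ratio; 0 for a constant trajectory.
#' @export
relative_volatility <- function(freq, all_sds,
                                sd_variant = c("population", "sample")) {
  if (length(all_sds) == 0L || mean(all_sds) <= 0) {
    rlang::abort("Degenerate corpus: mean of pooled SDs must be positive.")
  }
  trajectory_sd(freq, match.arg(sd_variant)) / mean(all_sds)
}

#' Quintile rank scores (1-5)
#'
#' Maps each value to its quintile by percentile rank: the top 20% score 5,
#' the bottom 20% score 1. Ties receive the score of their mean percentile
#' rank (so an all-equal column maps to the mid band, 3). With distinct
#' values, band sizes differ by at most one.
#'
#' @param values Numeric vector (length >= 5).
#' @param higher_is_better If `FALSE`, small values score high.
#' @return Integer vector of scores in 1..5.
#' @export
rank_scores <- function(values, higher_is_better = TRUE) {
  n <- length(values)
  if (n < 5L) rlang::abort("Need at least 5 values to band into quintiles.")
  v <- if (higher_is_better) values else -values
  r <- rank(v, ties.method = "average")
  as.integer(ceiling(5 * r / n))
}

#' Flag stoplisted terms
#'
#' Stoplists are named classes of terms to exclude from categorization, e.g.
#' time-of-day, person, and body-site words that do not narrow an injury
#' mechanism. Matching is exact on the token.
#'
#' @param terms Character vector of terms.
#' @param stoplist Named list of character vectors (e.g.
#'   `list(time = c("morning", ...), person = ..., body_site = ...)`), or
#'   `NULL` for no exclusions.
#' @return Tibble with columns `term`, `excluded`, `excluded_reason` (the
#'   class name, or `NA` when retained).
#' @export
apply_stoplist <- function(terms, stoplist = NULL) {
  reason <- rep(NA_character_, length(terms))
  if (!is.null(stoplist)) {
    if (is.null(names(stoplist)) || any(!nzchar(names(stoplist)))) {
      rlang::abort("`stoplist` must be a named list of term vectors.")
    }
    for (cls in names(stoplist)) {
      hit <- terms %in% stoplist[[cls]] & is.na(reason)
      reason[hit] <- cls
    }
  }
  tibble::tibble(term = terms, excluded = !is.na(reason),
                 excluded_reason = reason)
}

#' Assign a category from the three rank scores
#'
#' @param score_freq,score_accel,score_vol Integer scores in 1..5
#'   (vectorized).
#' @return Character vector: `"hazardous"`, `"noteworthy"`, `"diffusion"` or
#'   `"unclassified"`. The three rules cannot co-fire.
#' @export
categorize_scores <- function(score_freq, score_accel, score_vol) {
  s <- c(score_freq, score_accel, score_vol)
  if (any(is.na(s)) || any(s < 1 | s > 5) || any(s != as.integer(s))) {
    rlang::abort("Scores must be integers in 1..5.")
  }
  out <- rep("unclassified", length(score_freq))
  out[score_freq >= 4 & score_accel >= 4 & score_vol >= 4] <- "hazardous"
  out[score_freq <= 2 & score_accel >= 3 & score_vol >= 3] <- "noteworthy"
  out[score_freq >= 4 & score_accel <= 2] <- "diffusion"
  out
}

#' Assess candidate keywords: metrics, scores, category
#'
#' Computes average frequency, average acceleration and relative volatility
#' for each candidate term's trajectory, converts each metric to a quintile
#' score over the candidate pool, applies the stoplist, and assigns
#' categories. Scores are banded over all candidates before stoplist
#' exclusion; excluded terms keep their scores but receive no category.
#'
#' @param trajectories Tibble from [term_trajectories()] (columns `term`,
#'   `year`, `df`), restricted to the candidate terms.
#' @param study_years Integer vector of study years.
#' @param stoplist Passed to [apply_stoplist()].
#' @param accel_variant Passed to [average_acceleration()].
#' @param sd_variant Passed to [trajectory_sd()].
#' @return Tibble with one row per term: the three metrics, three scores,
#'   `category`, `excluded`, `excluded_reason`. Attribute `n_accel_undefined`
#'   counts trajectories too short for an acceleration.
#' @export
assess_keywords <- function(trajectories,
                            study_years = sort(unique(trajectories$year)),
                            stoplist = NULL,
                            accel_variant = c("first_difference",
                                              "second_difference"),
                            sd_variant = c("population", "sample")) {
  accel_variant <- match.arg(accel_variant)
  sd_variant <- match.arg(sd_variant)
  study_years <- sort(as.integer(study_years))
  n_years <- length(study_years)

  wide <- tidyr::pivot_wider(
    trajectories[trajectories$year %in% study_years, ],
    id_cols = "term", names_from = "year", values_from = "df",
    values_fill = 0L
  )
  wide <- wide[order(wide$term), , drop = FALSE]
  fmat <- as.matrix(wide[, as.character(study_years), drop = FALSE])
  terms <- wide$term
  if (length(terms) < 5L) {
    rlang::abort("Need at least 5 candidate terms to band scores.")
  }

  avg_freq <- apply(fmat, 1L, average_frequency, n_years = n_years)
  accels <- lapply(seq_along(terms), function(i) {
    average_acceleration(fmat[i, ], variant = accel_variant)
  })
  avg_accel <- vapply(accels, as.numeric, numeric(1))
  n_undef <- sum(vapply(accels, function(a) isTRUE(attr(a, "undefined")),
                        logical(1)))
  sds <- apply(fmat, 1L, trajectory_sd, variant = sd_variant)
  rel_vol <- vapply(seq_along(terms), function(i) {
    relative_volatility(fmat[i, ], sds, sd_variant = sd_variant)
  }, numeric(1))

  score_freq <- rank_scores(avg_freq)
  score_accel <- rank_scores(avg_accel)
  score_vol <- rank_scores(rel_vol)
  stop_tbl <- apply_stoplist(terms, stoplist)
  category <- categorize_scores(score_freq, score_accel, score_vol)
  category[stop_tbl$excluded] <- NA_character_

  out <- tibble::tibble(
    term = terms,
    avg_freq = avg_freq,
    avg_accel = avg_accel,
    rel_volatility = rel_vol,
    score_freq = score_freq,
    score_accel = score_accel,
    score_vol = score_vol,
    category = category,
    excluded = stop_tbl$excluded,
    excluded_reason = stop_tbl$excluded_reason
  )
  attr(out, "n_accel_undefined") <- n_undef
  out
}

#' Per-category summary
#'
#' @param assessments Output of [assess_keywords()].
#' @param n_representative How many top terms (by average frequency) to list
#'   per category.
#' @return Tibble: category, N, means of the three metrics, representative
#'   terms (comma-separated).
#' @export
category_summary <- function(assessments, n_representative = 5L) {
  kept <- assessments[!assessments$excluded & !is.na(assessments$category), ]
  by_cat <- dplyr::group_by(kept, .data$category)
  dplyr::summarise(
    by_cat,
    n = dplyr::n(),
    mean_avg_freq = mean(.data$avg_freq),
    mean_avg_accel = mean(.data$avg_accel),
    mean_rel_volatility = mean(.data$rel_volatility),
    representative = paste(
      head(.data$term[order(-.data$avg_freq)], n_representative),
      collapse = ", "
    ),
    .groups = "drop"
  )
}
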