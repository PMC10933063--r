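# TF-IDF term importance: per-year weights under the max-TF convention and
# top-K candidate keyword selection by average annual weight.

#' Term frequency within a document
#'
#' The proportion of a document's tokens that are the term:
#' `TF = n(term in doc) / n(tokens in doc)`.
#'
#' @param term_count_in_doc Occurrences of the term in the document.
#' @param doc_token_total Total tokens in the document (>= 1).
#' @return Proportion in `[0, 1]`. Vectorized.
#' @export
tf <- function(term_count_in_doc, doc_token_total) {
  if (any(doc_token_total < 1)) {
    rlang::abort("Zero-length document: should have been dropped upstream.")
  }
  if (any(term_count_in_doc < 0) || any(term_count_in_doc > doc_token_total)) {
    rlang::abort("`term_count_in_doc` must lie in [0, doc_token_total].")
  }
  term_count_in_doc / doc_token_total
}

#' Inverse document frequency
#'
#' `IDF = ln(n_docs / n_docs_with_term)`, natural log, no smoothing. Zero
#' exactly when the term occurs in every document.
#'
#' @param n_docs Total documents in the year.
#' @param n_docs_with_term Documents containing the term (>= 1).
#' @return Non-negative real. Vectorized.
#' @export
idf <- function(n_docs, n_docs_with_term) {
  if (any(n_docs_with_term < 1)) {
    rlang::abort("Term not in corpus: `n_docs_with_term` must be >= 1.")
  }
  if (any(n_docs_with_term > n_docs)) {
    rlang::abort("`n_docs_with_term` cannot exceed `n_docs`.")
  }
  log(n_docs / n_docs_with_term)
}

#' Yearly TF-IDF weights under the max-TF convention
#'
#' For every term retained in the (downsized) matrix, computes the maximum TF
#' over the year's documents containing the term, the year's IDF, and their
#' product.
#'
#' @param m A `term_matrix` (one year, downsized).
#' @return Tibble with columns `term`, `year`, `tf_max`, `idf`, `tfidf`,
#'   sorted by term.
#' @export
yearly_tfidf <- function(m) {
  counts <- m$counts
  terms <- colnames(counts)
  nd <- nrow(counts)
  if (length(terms) == 0L) {
    return(tibble::tibble(term = character(), year = integer(),
                          tf_max = numeric(), idf = numeric(),
                          tfidf = numeric()))
  }
  tfm <- Matrix::Diagonal(x = 1 / m$doc_token_total) %*% counts
  trip <- Matrix::summary(methods::as(tfm, "TsparseMatrix"))
  tf_max <- rep(0, length(terms))
  agg <- tapply(trip$x, trip$j, max)
  tf_max[as.integer(names(agg))] <- as.numeric(agg)
  dfv <- doc_freq(m)
  tibble::tibble(
    term = terms,
    year = m$year,
    tf_max = tf_max,
    idf = idf(nd, as.numeric(dfv)),
    tfidf = tf_max * idf(nd, as.numeric(dfv))
  )
}

#' Select candidate injury keywords by average annual TF-IDF
#'
#' Averages each term's yearly TF-IDF weights over the study years and keeps
#' the top `k`. Under the default `"zero_fill"` policy a year in which the
#' term is absent (or was removed by downsizing) contributes zero, so the
#' average is the sum of weights divided by the number of study years;
#' `"observed"` averages over the years the term actually has a weight.
#' Ties are broken lexicographically after rounding the average to 12
#' decimals, so rankings are stable across platforms.
#'
#' @param weights Tibble of yearly weights, rows from [yearly_tfidf()] across
#'   years (columns `term`, `year`, `tfidf`).
#' @param k Number of candidates to keep (default 300). When fewer terms are
#'   available, all are returned with a warning.
#' @param study_years Integer vector of study years (defaults to the distinct
#'   years present in `weights`).
#' @param missing_year_policy `"zero_fill"` (default) or `"observed"`.
#' @return Tibble with columns `term`, `avg_tfidf`, `n_years_present`,
#'   `rank`, plus a list-column `yearly` of named per-year weights; sorted by
#'   rank.
#' @export
select_candidates <- function(weights, k = 300,
                              study_years = sort(unique(weights$year)),
                              missing_year_policy = c("zero_fill", "observed")) {
  missing_year_policy <- match.arg(missing_year_policy)
  if (!is_count(k, min = 1L)) rlang::abort("`k` must be a count >= 1.")
  n_years <- length(study_years)
  if (n_years == 0L) rlang::abort("`study_years` must be non-empty.")

  by_term <- dplyr::group_by(weights, .data$term)
  agg <- dplyr::summarise(
    by_term,
    total = sum(.data$tfidf),
    n_years_present = dplyr::n(),
    yearly = list(setNames(.data$tfidf, .data$year)),
    .groups = "drop"
  )
  agg$avg_tfidf <- switch(missing_year_policy,
    zero_fill = agg$total / n_years,
    observed = agg$total / agg$n_years_present
  )
  key <- round(agg$avg_tfidf, 12)
  ord <- order(-key, agg$term)
  agg <- agg[ord, , drop = FALSE]
  if (nrow(agg) < k) {
    rlang::warn(sprintf("Only %d terms available; returning all (k = %d).",
                        nrow(agg), k))
    k <- nrow(agg)
  }
  out <- agg[seq_len(k), c("term", "avg_tfidf", "n_years_present", "yearly")]
  out$rank <- seq_len(k)
  out[, c("term", "avg_tfidf", "n_years_present", "rank", "yearly")]
}

#' Wide candidate table (one column per study year)
#'
#' Mirrors the layout of a published candidate-keyword table: term, one
#' TF-IDF column per year (NA when the term had no weight that year), the
#' average, and the rank.
#'
#' @param candidates Output of [select_candidates()].
#' @param study_years Integer vector of study years.
#' @return Tibble with `term`, one `y<year>` column per year, `avg_tfidf`,
#'   `rank`.
#' @export
candidate_table <- function(candidates, study_years) {
  study_years <- sort(as.integer(study_years))
  cols <- lapply(study_years, function(y) {
    vapply(candidates$yearly, function(w) {
      yy <- as.character(y)
      if (yy %in% names(w)) unname(w[[yy]]) else NA_real_
    }, numeric(1))
  })
  names(cols) <- paste0("y", study_years)
  dplyr::bind_cols(
    tibble::tibble(term = candidates$term),
    tibble::as_tibble(cols),
    tibble::tibble(avg_tfidf = candidates$avg_tfidf, rank = candidates$rank)
  )
}
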