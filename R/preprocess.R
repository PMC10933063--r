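# From raw incident records to per-year term-document matrices, document
# frequency downsizing, and yearly term trajectories.

#' Construct a table of incident records
#'
#' An incident record is one casualty event: an identifier, the calendar year
#' of the event, and the free-text evaluation-findings narrative written by
#' the responding paramedic.
#'
#' @param id Character or integer vector of unique record identifiers.
#' @param year Integer vector of calendar years.
#' @param text Character vector of narratives.
#' @return A tibble with columns `id`, `year`, `text`.
#' @export
incident_records <- function(id, year, text) {
  if (length(id) != length(year) || length(id) != length(text)) {
    rlang::abort("`id`, `year` and `text` must have the same length.")
  }
  id <- as.character(id)
  if (anyDuplicated(id)) rlang::abort("Record ids must be unique.")
  year <- as.integer(year)
  if (anyNA(year)) rlang::abort("`year` must not contain missing values.")
  tibble::tibble(id = id, year = year, text = as.character(text))
}

#' A term-document matrix for one year of incidents
#'
#' Bundles the sparse count matrix (documents x terms) with the per-document
#' token totals needed as TF denominators. Token totals are frozen at
#' construction, before any downsizing, so removing rare terms never changes
#' a TF denominator.
#'
#' @param year Calendar year (or `NA` for a pooled multi-year matrix).
#' @param counts A [Matrix::sparseMatrix()] of token counts, documents in
#'   rows (dimnames required).
#' @param doc_token_total Named numeric vector of total tokens per document.
#' @return An object of class `term_matrix`.
#' @export
term_matrix <- function(year, counts, doc_token_total) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    rlang::abort("`counts` must carry document and term dimnames.")
  }
  if (!identical(rownames(counts), names(doc_token_total))) {
    rlang::abort("`doc_token_total` names must match the matrix rows.")
  }
  structure(
    list(
      year = as.integer(year),
      counts = methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix"),
      doc_token_total = doc_token_total
    ),
    class = "term_matrix"
  )
}

#' @export
print.term_matrix <- function(x, ...) {
  cat(sprintf(
    "<term_matrix> year %s: %d documents x %d terms\n",
    ifelse(is.na(x$year), "(pooled)", x$year),
    nrow(x$counts), ncol(x$counts)
  ))
  invisible(x)
}

#' Number of documents in a term matrix
#' @param m A `term_matrix`.
#' @return Integer document count.
#' @export
n_docs <- function(m) nrow(m$counts)

#' Document frequency of every retained term
#' @param m A `term_matrix`.
#' @return Named integer vector: number of documents containing each term.
#' @export
doc_freq <- function(m) {
  df <- Matrix::colSums(m$counts > 0)
  storage.mode(df) <- "integer"
  df
}

# Build one sparse matrix from pre-tokenized documents.
build_one_matrix <- function(ids, token_lists, year) {
  lens <- lengths(token_lists)
  doc_idx <- rep.int(seq_along(ids), lens)
  toks <- unlist(token_lists, use.names = FALSE)
  terms <- sort(unique(toks))
  counts <- Matrix::sparseMatrix(
    i = doc_idx,
    j = match(toks, terms),
    x = 1,
    dims = c(length(ids), length(terms)),
    dimnames = list(ids, terms)
  )
  term_matrix(year, counts, setNames(as.numeric(lens), ids))
}

#' Build per-year term-document matrices
#'
#' Tokenizes every narrative and assembles one term-document matrix per
#' distinct year (or one pooled matrix across years). Records that tokenize
#' to nothing are dropped; the number dropped is attached as attribute
#' `n_dropped` and reported via a message.
#'
#' @param records Tibble of incident records (see [incident_records()]).
#' @inheritParams get_tokenizer
#' @param by_year If `TRUE` (default) return a named list with one
#'   `term_matrix` per year, in year order; if `FALSE` return a single pooled
#'   `term_matrix` with `year = NA`.
#' @return List of `term_matrix` objects (or a single one when
#'   `by_year = FALSE`), with attribute `n_dropped`.
#' @export
build_matrix <- function(records, tokenizer = "default", by_year = TRUE) {
  if (nrow(records) == 0L) rlang::abort("`records` must be non-empty.")
  token_lists <- tokenize_all(records$text, tokenizer)
  keep <- lengths(token_lists) > 0L
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    rlang::inform(sprintf("Dropped %d record(s) empty after tokenization.",
                          n_dropped))
  }
  if (!any(keep)) {
    rlang::abort("All records are empty after tokenization.")
  }
  records <- records[keep, , drop = FALSE]
  token_lists <- token_lists[keep]

  if (!by_year) {
    out <- build_one_matrix(records$id, token_lists, NA_integer_)
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  years <- sort(unique(records$year))
  out <- lapply(years, function(y) {
    sel <- records$year == y
    build_one_matrix(records$id[sel], token_lists[sel], y)
  })
  names(out) <- as.character(years)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Downsize a term matrix by document frequency
#'
#' Retains exactly the terms appearing in at least `min_df` documents of the
#' matrix. Document token totals are left untouched: TF denominators always
#' refer to the full written narrative. Idempotent.
#'
#' @param m A `term_matrix`.
#' @param min_df Minimum document frequency; the threshold is inclusive
#'   (`DF >= min_df` is retained). Default 10.
#' @return A `term_matrix` restricted to the retained terms, with attribute
#'   `n_terms_removed`.
#' @export
downsize <- function(m, min_df = 10) {
  if (!is_count(min_df, min = 1L)) rlang::abort("`min_df` must be a count >= 1.")
  df <- doc_freq(m)
  keep <- df >= min_df
  out <- term_matrix(m$year, m$counts[, keep, drop = FALSE], m$doc_token_total)
  attr(out, "n_terms_removed") <- sum(!keep)
  if (!any(keep)) rlang::inform("Downsizing removed every term.")
  out
}

#' Union of retained terms across years
#'
#' @param matrices List of `term_matrix` objects (typically downsized).
#' @return Sorted character vector of distinct terms.
#' @export
union_terms <- function(matrices) {
  if (length(matrices) == 0L) rlang::abort("Need at least one matrix.")
  sort(unique(unlist(lapply(matrices, function(m) colnames(m$counts)),
                     use.names = FALSE)))
}

#' Yearly document-frequency trajectories
#'
#' Returns a complete term x study-year grid of document frequencies,
#' zero-filled for years in which a term does not appear. Frequencies are
#' read from the matrices as given; pass the raw (pre-downsizing) matrices so
#' a year in which a term fell below the DF threshold still contributes its
#' true count.
#'
#' @param matrices Named list of per-year `term_matrix` objects.
#' @param terms Character vector of terms to track.
#' @param study_years Integer vector of study years (defaults to the years of
#'   `matrices`).
#' @return Tibble with columns `term`, `year`, `df`.
#' @export
term_trajectories <- function(matrices, terms,
                              study_years = vapply(matrices, `[[`, 1L, "year")) {
  study_years <- sort(as.integer(study_years))
  grid <- tidyr::expand_grid(term = sort(unique(terms)), year = study_years)
  obs <- dplyr::bind_rows(lapply(matrices, function(m) {
    df <- doc_freq(m)
    sel <- intersect(names(df), terms)
    tibble::tibble(term = sel, year = m$year, df = as.integer(df[sel]))
  }))
  out <- dplyr::left_join(grid, obs, by = c("term", "year"))
  out$df[is.na(out$df)] <- 0L
  out
}

#' Per-year term summary table
#'
#' One row per (year, term): document frequency and the per-term maximum TF.
#' Convenience export mirroring the yearly term-document summaries written by
#' the pipeline.
#'
#' @param matrices Named list of per-year `term_matrix` objects.
#' @return Tibble with columns `year`, `term`, `df`, `tf_max`.
#' @export
yearly_term_summary <- function(matrices) {
  dplyr::bind_rows(lapply(matrices, function(m) {
    w <- yearly_tfidf(m)
    df <- doc_freq(m)
    tibble::tibble(year = m$year, term = w$term,
                   df = as.integer(df[w$term]), tf_max = w$tf_max)
  }))
}
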