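# Independent oracles and small fixture builders used across the suite.

toy_corpus_path <- function() {
  system.file("extdata", "toy_corpus.csv", package = "injurymine")
}

# Naive two-loop TF-IDF over pre-tokenized documents of one year: for each
# term, loop over documents for max TF, then multiply by ln(N / DF).
naive_tfidf_oracle <- function(token_lists) {
  n <- length(token_lists)
  terms <- sort(unique(unlist(token_lists)))
  out <- data.frame(term = terms, tf_max = NA_real_, idf = NA_real_,
                    tfidf = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(terms)) {
    t <- terms[k]
    tf_max <- 0
    df <- 0
    for (d in token_lists) {
      cnt <- sum(d == t)
      if (cnt > 0) {
        df <- df + 1
        tf_max <- max(tf_max, cnt / length(d))
      }
    }
    out$tf_max[k] <- tf_max
    out$idf[k] <- log(n / df)
    out$tfidf[k] <- tf_max * log(n / df)
  }
  out
}

# Pearson-correlation oracle for the phi coefficient: expand the 2x2 table
# into two binary indicator vectors and correlate them.
pearson_phi_oracle <- function(a, b, c, d) {
  x <- c(rep(1, a), rep(1, b), rep(0, c), rep(0, d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  suppressWarnings(stats::cor(x, y))
}

# All set partitions of n elements (restricted growth strings); n <= 8.
set_partitions <- function(n) {
  out <- list()
  rec <- function(a, mx) {
    if (length(a) == n) {
      out[[length(out) + 1L]] <<- a
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(a, v), max(mx, v))
  }
  rec(integer(), 0L)
  out
}

# Exhaustive modularity maximum over every partition of a small graph.
brute_force_max_modularity <- function(graph, weights = NULL) {
  parts <- set_partitions(igraph::vcount(graph))
  max(vapply(parts, function(p) {
    igraph::modularity(graph, p, weights = weights)
  }, numeric(1)))
}

# One-year record set from bare texts.
records_from_texts <- function(texts, year = 2020L) {
  incident_records(sprintf("D%03d", seq_along(texts)), rep(year, length(texts)),
                   texts)
}
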