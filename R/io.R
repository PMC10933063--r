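# Reading and writing the pipeline's record-oriented text formats. Corpora
# travel as JSON-lines ({"id","year","text"}) or CSV with the same columns.

#' Read an incident corpus
#'
#' Format is inferred from the extension (`.jsonl`/`.json` vs `.csv`) unless
#' given explicitly.
#'
#' @param path File path.
#' @param format `"jsonl"`, `"csv"` or `"auto"` (default).
#' @return Incident records tibble.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("Input file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    return(incident_records(df$id, as.integer(df$year), df$text))
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  incident_records(
    vapply(recs, function(r) as.character(r$id), character(1)),
    vapply(recs, function(r) as.integer(r$year), integer(1)),
    vapply(recs, function(r) as.character(r$text), character(1))
  )
}

#' Write an incident corpus
#'
#' @param records Incident records tibble.
#' @param path Output path.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(records, path, row.names = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      jsonlite::toJSON(list(id = records$id[i], year = records$year[i],
                            text = records$text[i]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Write ground-truth categories
#'
#' @param truth Tibble from [ground_truth()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

# Deterministic CSV writer used for all pipeline outputs (fixed field order,
# no row names, '.' decimal, UTF-8).
write_stage_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.factor(df[[col]])) df[[col]] <- as.character(df[[col]])
  }
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
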