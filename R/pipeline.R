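# End-to-end orchestration: preprocess -> importance -> categorize ->
# network, from a single validated config, with reproducible outputs and an
# accounting manifest.

#' Pipeline configuration
#'
#' Every analysis threshold is surfaced as a named parameter with its
#' conventional default: DF threshold 10, top 300 candidates, phi link
#' filter 0.05, minimum pair support 10.
#'
#' @param input Path to a corpus file (JSON-lines or CSV), or `NULL` when
#'   `records` is supplied directly.
#' @param records In-memory incident records tibble (alternative to
#'   `input`).
#' @param study_years Integer vector of study years, or `NULL` to use the
#'   years present in the corpus.
#' @param min_df Document-frequency threshold (inclusive).
#' @param top_k Number of candidate keywords.
#' @param missing_year_policy `"zero_fill"` or `"observed"` (see
#'   [select_candidates()]).
#' @param accel_variant `"first_difference"` or `"second_difference"`.
#' @param sd_variant `"population"` or `"sample"`.
#' @param stoplist Named list of stoplist term vectors, or a path to a YAML
#'   file holding one, or `NULL`.
#' @param egos Explicit ego terms for the network stage; default `NULL`
#'   uses the hazardous-category keywords found by the categorize stage.
#' @param phi_threshold Minimum phi for a retained link.
#' @param min_cooccurrence Minimum documents containing both terms of a
#'   pair.
#' @param phi_filter_order `"ego_first"` or `"phi_first"`.
#' @param louvain_resolution Resolution parameter for community detection.
#' @param tokenizer Tokenizer name or function.
#' @param seed Integer seed for the stochastic stages.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, records = NULL, study_years = NULL,
                            min_df = 10, top_k = 300,
                            missing_year_policy = "zero_fill",
                            accel_variant = "first_difference",
                            sd_variant = "population",
                            stoplist = NULL, egos = NULL,
                            phi_threshold = 0.05, min_cooccurrence = 10,
                            phi_filter_order = "ego_first",
                            louvain_resolution = 1,
                            tokenizer = "default", seed = 1L,
                            out_dir = NULL) {
  if (is.character(stoplist) && length(stoplist) == 1L) {
    stoplist <- yaml::read_yaml(stoplist)
    stoplist <- lapply(stoplist, as.character)
  }
  structure(
    list(input = input, records = records, study_years = study_years,
         min_df = min_df, top_k = top_k,
         missing_year_policy = missing_year_policy,
         accel_variant = accel_variant, sd_variant = sd_variant,
         stoplist = stoplist, egos = egos,
         phi_threshold = phi_threshold,
         min_cooccurrence = min_cooccurrence,
         phi_filter_order = phi_filter_order,
         louvain_resolution = louvain_resolution,
         tokenizer = tokenizer, seed = seed, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @return Character vector of violations, each naming the offending field;
#'   empty when the config is valid.
#' @export
validate_config <- function(config) {
  v <- character()
  bad <- function(msg) v <<- c(v, msg)
  if (is.null(config$input) && is.null(config$records)) {
    bad("input: either `input` or `records` must be provided")
  }
  if (!is.null(config$input) && !is.null(config$records)) {
    bad("input: provide `input` or `records`, not both")
  }
  if (!is.null(config$input) && !file.exists(config$input)) {
    bad(sprintf("input: file does not exist: %s", config$input))
  }
  if (!is_count(config$min_df, min = 1L)) {
    bad("min_df: must be a count >= 1")
  }
  if (!is_count(config$top_k, min = 1L)) {
    bad("top_k: must be a count >= 1")
  }
  if (!config$missing_year_policy %in% c("zero_fill", "observed")) {
    bad("missing_year_policy: must be 'zero_fill' or 'observed'")
  }
  if (!config$accel_variant %in% c("first_difference", "second_difference")) {
    bad("accel_variant: must be 'first_difference' or 'second_difference'")
  }
  if (!config$sd_variant %in% c("population", "sample")) {
    bad("sd_variant: must be 'population' or 'sample'")
  }
  if (!is.numeric(config$phi_threshold) || config$phi_threshold < 0 ||
      config$phi_threshold > 1) {
    bad("phi_threshold: must lie in [0, 1]")
  }
  if (!is_count(config$min_cooccurrence, min = 0L)) {
    bad("min_cooccurrence: must be a count >= 0")
  }
  if (!config$phi_filter_order %in% c("ego_first", "phi_first")) {
    bad("phi_filter_order: must be 'ego_first' or 'phi_first'")
  }
  if (!is.null(config$study_years)) {
    ys <- sort(as.integer(config$study_years))
    if (length(ys) && !all(diff(ys) == 1L)) {
      bad("study_years: must be contiguous")
    }
  }
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    bad("seed: required (community detection is stochastic)")
  }
  if (!is.null(config$stoplist) &&
      (!is.list(config$stoplist) || is.null(names(config$stoplist)))) {
    bad("stoplist: must be a named list of term vectors")
  }
  v
}

#' Run the full emerging-injury-issue pipeline
#'
#' Executes preprocess, importance, categorize and network in order, writing
#' stage outputs and a run manifest under `config$out_dir` when set.
#' Re-running with identical config and inputs reproduces byte-identical
#' outputs. The network stage is skipped (and recorded as such) when no
#' hazardous keyword is found and no explicit egos were configured.
#'
#' @param config A validated [pipeline_config()].
#' @return A list with the stage results (`matrices_raw` omitted for size):
#'   `candidates`, `assessments`, `summary`, `graph`, `partition`, `report`,
#'   and `manifest` (config echo, input hash, per-stage counts).
#' @export
run_pipeline <- function(config) {
  violations <- validate_config(config)
  if (length(violations)) {
    stopf("Invalid config:\n%s", paste("-", violations, collapse = "\n"))
  }

  records <- if (!is.null(config$records)) config$records
             else read_corpus(config$input)
  input_hash <- if (!is.null(config$input)) {
    unname(tools::md5sum(config$input))
  } else {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    write.csv(records, tmp, row.names = FALSE)
    unname(tools::md5sum(tmp))
  }

  study_years <- config$study_years %||% sort(unique(records$year))
  study_years <- sort(as.integer(study_years))
  records <- records[records$year %in% study_years, , drop = FALSE]
  if (nrow(records) == 0L) rlang::abort("No records within the study years.")

  counts <- list(n_records = nrow(records))
  stages <- character()

  # -- preprocess --
  raw <- build_matrix(records, config$tokenizer, by_year = TRUE)
  counts$n_dropped_empty <- attr(raw, "n_dropped")
  down <- lapply(raw, downsize, min_df = config$min_df)
  counts$n_terms_removed_df <- vapply(down, function(m) {
    attr(m, "n_terms_removed")
  }, integer(1))
  terms <- union_terms(down)
  counts$n_terms_union <- length(terms)
  stages <- c(stages, "preprocess")

  # -- importance --
  weights <- dplyr::bind_rows(lapply(down, yearly_tfidf))
  candidates <- select_candidates(
    weights, k = config$top_k, study_years = study_years,
    missing_year_policy = config$missing_year_policy
  )
  counts$n_candidates <- nrow(candidates)
  stages <- c(stages, "importance")

  # -- categorize --
  traj <- term_trajectories(raw, candidates$term, study_years)
  assessments <- assess_keywords(
    traj, study_years, stoplist = config$stoplist,
    accel_variant = config$accel_variant, sd_variant = config$sd_variant
  )
  counts$n_stoplisted <- sum(assessments$excluded)
  counts$n_accel_undefined <- attr(assessments, "n_accel_undefined")
  summary_tbl <- category_summary(assessments)
  counts$category_counts <- as.list(setNames(
    as.integer(summary_tbl$n), summary_tbl$category
  ))
  stages <- c(stages, "categorize")

  # -- network --
  egos <- config$egos %||%
    assessments$term[!is.na(assessments$category) &
                       assessments$category == "hazardous"]
  graph <- NULL
  partition <- NULL
  report <- NULL
  if (length(egos) == 0L) {
    stages <- c(stages, "network:skipped (no ego terms)")
  } else {
    graph <- build_graph(
      records, egos, tokenizer = config$tokenizer, min_df = config$min_df,
      phi_threshold = config$phi_threshold,
      min_cooccurrence = config$min_cooccurrence,
      filter_order = config$phi_filter_order
    )
    partition <- louvain_communities(
      graph, seed = config$seed, resolution = config$louvain_resolution
    )
    report <- degree_report(graph, partition)
    counts$n_nodes <- igraph::vcount(graph)
    counts$n_edges <- igraph::ecount(graph)
    counts$n_pairs_skipped <- igraph::graph_attr(graph, "n_pairs_skipped")
    counts$n_communities <- partition$n_communities
    stages <- c(stages, "network")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("injurymine")),
    config = config[setdiff(names(config), c("records", "out_dir"))],
    input_md5 = input_hash,
    study_years = study_years,
    stages = stages,
    counts = counts
  )

  result <- list(
    candidates = candidates,
    assessments = assessments,
    summary = summary_tbl,
    graph = graph,
    partition = partition,
    report = report,
    manifest = manifest
  )
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, config$out_dir, study_years)
  }
  result
}

# Write every stage output with deterministic formatting.
write_pipeline_outputs <- function(result, out_dir, study_years) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_stage_csv(candidate_table(result$candidates, study_years),
                  p("candidates.csv"))
  write_stage_csv(result$assessments, p("assessments.csv"))
  write_stage_csv(result$summary, p("category_summary.csv"))
  if (!is.null(result$graph)) {
    write_stage_csv(graph_edges(result$graph), p("edges.csv"))
    write_stage_csv(result$report$nodes, p("communities.csv"))
    igraph::write_graph(result$graph, p("network.graphml"),
                        format = "graphml")
    net_summary <- list(
      n_nodes = igraph::vcount(result$graph),
      n_edges = igraph::ecount(result$graph),
      modularity = result$partition$modularity,
      n_communities = result$partition$n_communities
    )
    jsonlite::write_json(net_summary, p("network_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- result$manifest
  manifest$config$tokenizer <-
    if (is.function(manifest$config$tokenizer)) "<function>"
    else manifest$config$tokenizer
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}
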