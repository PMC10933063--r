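# Phi-coefficient semantic network around hazardous-accident keywords:
# sub-corpus selection, pairwise 2x2 contingency tables, ego-network
# extraction, link filtering, and Louvain community detection.

#' Phi coefficient of a 2x2 term contingency table
#'
#' For two terms with cell counts `a` (documents containing both), `b`
#' (first only), `c` (second only) and `d` (neither),
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`. This equals the Pearson
#' correlation of the two binary presence indicators.
#'
#' Pairs with a zero marginal have no defined correlation and yield `NA`
#' (they are skipped, with a message, when building a graph).
#'
#' @param a,b,c,d Non-negative cell counts (vectorized).
#' @return Phi in `[-1, 1]`, or `NA` where a marginal is zero.
#' @export
#' @examples
#' phi_coefficient(30, 10, 10, 50)  # 1400/2400
phi_coefficient <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) rlang::abort("Cell counts must be >= 0.")
  denom2 <- (a + b) * (c + d) * (a + c) * (b + d)
  out <- rep(NA_real_, length(denom2))
  ok <- denom2 > 0
  out[ok] <- ((a * d - b * c)[ok]) / sqrt(denom2[ok])
  out
}

#' Correlation-strength band of a retained link
#'
#' Bands: weak `[0.05, 0.10)`, moderate `[0.10, 0.15)`, strong
#' `[0.15, 0.25)`, very strong `[0.25, 1]`. Links below 0.05 are filtered
#' upstream and have no band (`NA`).
#'
#' @param phi Numeric vector of phi values.
#' @return Factor with levels weak < moderate < strong < very_strong.
#' @export
classify_strength <- function(phi) {
  cut(phi, breaks = c(0.05, 0.10, 0.15, 0.25, Inf), right = FALSE,
      labels = c("weak", "moderate", "strong", "very_strong"),
      ordered_result = TRUE)
}

#' Select the sub-corpus of records mentioning any ego term
#'
#' @param records Incident records tibble.
#' @param ego_terms Character vector of focal (e.g. hazardous) keywords.
#' @inheritParams get_tokenizer
#' @return The matching records (a record with several ego terms counts
#'   once).
#' @export
select_subcorpus <- function(records, ego_terms, tokenizer = "default") {
  if (length(ego_terms) == 0L) rlang::abort("`ego_terms` must be non-empty.")
  toks <- tokenize_all(records$text, tokenizer)
  hit <- vapply(toks, function(tk) any(tk %in% ego_terms), logical(1))
  if (!any(hit)) {
    rlang::abort("No record contains any ego term; empty sub-corpus.")
  }
  records[hit, , drop = FALSE]
}

#' Build the phi-coefficient semantic ego network
#'
#' Pipeline: select records containing an ego term; build one pooled
#' term-document matrix over the sub-corpus and re-apply the document
#' frequency downsizing; count pairwise co-occurrences and keep pairs
#' supported by at least `min_cooccurrence` documents; compute phi from each
#' pair's 2x2 table (the `d` cell uses the sub-corpus document total);
#' extract the 1.5-degree ego network (egos, their direct neighbours, and
#' all links among the kept nodes); drop links with `phi < phi_threshold`;
#' remove isolated non-ego nodes. With `filter_order = "phi_first"` the phi
#' filter is applied before ego extraction instead.
#'
#' @param records Incident records tibble.
#' @param ego_terms Focal keywords (egos).
#' @inheritParams get_tokenizer
#' @param min_df Document-frequency threshold re-applied on the sub-corpus.
#' @param phi_threshold Minimum phi for a retained link (default 0.05).
#' @param min_cooccurrence Minimum number of documents containing both terms
#'   of a pair (default 10).
#' @param filter_order `"ego_first"` (default) or `"phi_first"`.
#' @return An [igraph::graph] with vertex attributes `name`, `is_ego` and
#'   edge attributes `phi`, `cooccurrence`, `band`; graph attributes
#'   `n_docs` (sub-corpus size) and `n_pairs_skipped` (zero-marginal pairs).
#' @export
build_graph <- function(records, ego_terms, tokenizer = "default",
                        min_df = 10, phi_threshold = 0.05,
                        min_cooccurrence = 10,
                        filter_order = c("ego_first", "phi_first")) {
  filter_order <- match.arg(filter_order)
  if (phi_threshold < 0 || phi_threshold > 1) {
    rlang::abort("`phi_threshold` must lie in [0, 1].")
  }
  if (!is_count(min_cooccurrence, min = 0L)) {
    rlang::abort("`min_cooccurrence` must be a count >= 0.")
  }

  sub <- select_subcorpus(records, ego_terms, tokenizer)
  m <- downsize(build_matrix(sub, tokenizer, by_year = FALSE), min_df = min_df)
  terms <- colnames(m$counts)
  if (length(terms) < 2L) rlang::abort("Sub-corpus has fewer than 2 terms.")
  x <- m$counts > 0
  nd <- nrow(x)
  co <- Matrix::crossprod(x * 1)            # terms x terms co-occurrence
  dfv <- Matrix::diag(co)

  co <- methods::as(methods::as(co, "generalMatrix"), "TsparseMatrix")
  sel <- co@i < co@j & co@x >= min_cooccurrence
  i <- co@i[sel] + 1L
  j <- co@j[sel] + 1L
  a <- co@x[sel]
  b <- dfv[i] - a
  cc <- dfv[j] - a
  d <- nd - a - b - cc
  phi <- phi_coefficient(a, b, cc, d)
  skipped <- sum(is.na(phi))
  if (skipped > 0L) {
    rlang::inform(sprintf("Skipped %d pair(s) with a zero marginal.", skipped))
  }
  edges <- tibble::tibble(
    term1 = terms[i], term2 = terms[j],
    phi = phi, cooccurrence = as.integer(a)
  )
  edges <- edges[!is.na(edges$phi), , drop = FALSE]

  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = sort(terms), stringsAsFactors = FALSE)
  )
  igraph::V(g)$is_ego <- igraph::V(g)$name %in% ego_terms

  drop_weak <- function(g) {
    igraph::delete_edges(g, igraph::E(g)[igraph::E(g)$phi < phi_threshold])
  }
  extract_ego <- function(g) {
    egos <- igraph::V(g)[igraph::V(g)$is_ego]
    if (length(egos) == 0L) {
      rlang::abort("No ego term survived downsizing of the sub-corpus.")
    }
    nbrs <- unique(unlist(igraph::adjacent_vertices(g, egos)))
    keep <- sort(unique(c(as.integer(egos), as.integer(nbrs))))
    igraph::induced_subgraph(g, keep)
  }

  g <- if (filter_order == "ego_first") drop_weak(extract_ego(g))
       else extract_ego(drop_weak(g))

  iso <- igraph::degree(g) == 0 & !igraph::V(g)$is_ego
  g <- igraph::delete_vertices(g, igraph::V(g)[iso])
  if (igraph::ecount(g) > 0L) {
    igraph::E(g)$band <- as.character(classify_strength(igraph::E(g)$phi))
  }
  g <- igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
  igraph::graph_attr(g, "n_docs") <- nd
  igraph::graph_attr(g, "n_pairs_skipped") <- skipped
  g
}

#' Louvain community detection with deterministic multi-restart
#'
#' Runs the Louvain modularity-optimization heuristic on the phi-weighted
#' graph several times under seeds derived deterministically from `seed`,
#' and keeps the partition with the highest (weighted) modularity; ties go
#' to the earliest restart. Community ids are renumbered by first appearance
#' in lexicographic vertex order, so identical inputs give identical output.
#'
#' @param graph Graph from [build_graph()] (edge attribute `phi` used as
#'   weight unless `weighted = FALSE`).
#' @param seed Integer seed.
#' @param resolution Resolution parameter of modularity (default 1).
#' @param n_restarts Number of seeded restarts (default 10).
#' @param weighted Use phi edge weights (default `TRUE`).
#' @return List of class `community_partition`: `assignment` (named integer
#'   vector), `modularity`, `n_communities`.
#' @export
louvain_communities <- function(graph, seed = 1L, resolution = 1,
                                n_restarts = 10L, weighted = TRUE) {
  if (igraph::vcount(graph) == 0L) rlang::abort("Graph has no nodes.")
  nm <- igraph::V(graph)$name
  w <- if (weighted && igraph::ecount(graph) > 0L) igraph::E(graph)$phi else NULL
  if (!is.null(w) && any(w < 0)) {
    rlang::abort("Edge weights must be non-negative for Louvain.")
  }

  if (igraph::ecount(graph) == 0L) {
    assignment <- setNames(seq_along(nm), nm)
    return(structure(list(assignment = assignment, modularity = 0,
                          n_communities = length(nm)),
                     class = "community_partition"))
  }

  best <- NULL
  best_mod <- -Inf
  for (r in seq_len(n_restarts)) {
    cl <- with_local_seed(seed + r - 1L, {
      igraph::cluster_louvain(graph, weights = w, resolution = resolution)
    })
    memb <- igraph::membership(cl)
    mod <- igraph::modularity(graph, memb, weights = w,
                              resolution = resolution)
    if (mod > best_mod + 1e-12) {
      best <- memb
      best_mod <- mod
    }
  }

  ord <- order(nm)
  relabel <- setNames(seq_along(unique(best[ord])), unique(best[ord]))
  assignment <- setNames(as.integer(relabel[as.character(best)]), nm)
  structure(
    list(assignment = assignment, modularity = best_mod,
         n_communities = length(unique(assignment))),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, modularity %.4f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

#' Modularity of the all-singletons partition
#'
#' Reference point for partition quality; always <= the optimized value.
#'
#' @inheritParams louvain_communities
#' @return Modularity of the partition placing every node alone.
#' @export
singleton_modularity <- function(graph, weighted = TRUE) {
  if (igraph::ecount(graph) == 0L) return(0)
  w <- if (weighted) igraph::E(graph)$phi else NULL
  igraph::modularity(graph, seq_len(igraph::vcount(graph)), weights = w)
}

#' Degree and community report
#'
#' @param graph Graph from [build_graph()].
#' @param partition Partition from [louvain_communities()].
#' @return List of two tibbles: `nodes` (term, degree, community, is_ego;
#'   sorted by degree descending then term) and `communities` (community,
#'   size, members).
#' @export
degree_report <- function(graph, partition) {
  nm <- igraph::V(graph)$name
  nodes <- tibble::tibble(
    term = nm,
    degree = as.integer(igraph::degree(graph)),
    community = as.integer(partition$assignment[nm]),
    is_ego = igraph::V(graph)$is_ego
  )
  nodes <- nodes[order(-nodes$degree, nodes$term), , drop = FALSE]
  by_comm <- dplyr::group_by(nodes, .data$community)
  communities <- dplyr::summarise(
    by_comm,
    size = dplyr::n(),
    members = paste(sort(.data$term), collapse = ", "),
    .groups = "drop"
  )
  list(nodes = nodes, communities = communities[order(-communities$size), ])
}

#' Edge list of a semantic graph as a tibble
#'
#' @param graph Graph from [build_graph()].
#' @return Tibble: term1, term2, phi, cooccurrence, band; term1 < term2,
#'   sorted.
#' @export
graph_edges <- function(graph) {
  if (igraph::ecount(graph) == 0L) {
    return(tibble::tibble(term1 = character(), term2 = character(),
                          phi = numeric(), cooccurrence = integer(),
                          band = character()))
  }
  el <- igraph::as_data_frame(graph, what = "edges")
  swap <- el$from > el$to
  t1 <- ifelse(swap, el$to, el$from)
  t2 <- ifelse(swap, el$from, el$to)
  out <- tibble::tibble(term1 = t1, term2 = t2, phi = el$phi,
                        cooccurrence = as.integer(el$cooccurrence),
                        band = el$band)
  out[order(out$term1, out$term2), , drop = FALSE]
}
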