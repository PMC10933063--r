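test_that("phi matches hand-worked contingency tables", {
  expect_equal(phi_coefficient(10, 0, 0, 10), 1)
  expect_equal(phi_coefficient(0, 10, 10, 0), -1)
  expect_equal(phi_coefficient(30, 10, 10, 50), 1400 / 2400)
  expect_true(is.na(phi_coefficient(5, 0, 5, 0)))  # zero marginal
  expect_error(phi_coefficient(-1, 2, 3, 4), ">= 0")
})

test_that("phi equals the Pearson correlation of binary indicators", {
  set.seed(123)
  for (i in 1:200) {
    cells <- sample(1:40, 4, replace = TRUE)  # positive marginals
    expect_lt(
      abs(phi_coefficient(cells[1], cells[2], cells[3], cells[4]) -
            pearson_phi_oracle(cells[1], cells[2], cells[3], cells[4])),
      1e-12
    )
  }
})

test_that("phi is symmetric and invariant under the (a,d)/(b,c) swap", {
  set.seed(7)
  for (i in 1:50) {
    x <- sample(0:30, 4, replace = TRUE)
    p <- phi_coefficient(x[1], x[2], x[3], x[4])
    expect_equal(phi_coefficient(x[1], x[3], x[2], x[4]), p)  # term order
    expect_equal(phi_coefficient(x[4], x[3], x[2], x[1]), p)  # a<->d, b<->c
  }
})

test_that("strength bands are half-open with 0.25 open-ended", {
  expect_equal(as.character(classify_strength(0.07)), "weak")
  expect_equal(as.character(classify_strength(0.10)), "moderate")
  expect_equal(as.character(classify_strength(0.16)), "strong")
  expect_equal(as.character(classify_strength(0.25)), "very_strong")
  expect_equal(as.character(classify_strength(0.9)), "very_strong")
  expect_true(is.na(classify_strength(0.049)))
})

test_that("select_subcorpus keeps records containing any ego term", {
  recs <- records_from_texts(c("fall from ladder", "burn oil", "cut knife"))
  got <- select_subcorpus(recs, "fall")
  expect_equal(nrow(got), 1L)
  expect_error(select_subcorpus(recs, "absent"), "No record")
  expect_error(select_subcorpus(recs, character()), "non-empty")
  # a record containing two egos is counted once
  two <- select_subcorpus(recs, c("fall", "ladder"))
  expect_equal(nrow(two), 1L)
})

test_that("build_graph keeps egos, neighbours and links among them", {
  # ccc/ddd co-occur with each other but never reach the support threshold
  # with an ego, so they are not ego neighbours and must be removed
  texts <- c(rep("ego1 aaa bbb", 6), rep("ego1 ccc ddd", 2),
             rep("ego2 ccc ddd", 2), rep("ego2 xfil", 2))
  g <- suppressMessages(
    build_graph(records_from_texts(texts), c("ego1", "ego2"), min_df = 1,
                phi_threshold = 0, min_cooccurrence = 3)
  )
  nm <- igraph::V(g)$name
  expect_true(all(c("ego1", "ego2", "aaa", "bbb") %in% nm))
  expect_false(any(c("ccc", "ddd") %in% nm))  # detached pair removed
  # link between two neighbours of the ego is retained
  expect_true(igraph::are_adjacent(g, "aaa", "bbb"))
})

test_that("links below the phi threshold are dropped, boundary inclusive", {
  texts <- c(rep("ego1 aaa bbb", 5), rep("ego1 aaa", 3),
             rep("ego2 bbb", 4), rep("ego2 zz1", 8))
  recs <- records_from_texts(texts)
  weak_phi <- phi_coefficient(5, 3, 4, 8)  # aaa vs bbb table in sub-corpus
  g_keep <- suppressMessages(
    build_graph(recs, c("ego1", "ego2"), min_df = 1, phi_threshold = 0,
                min_cooccurrence = 1)
  )
  expect_true(igraph::are_adjacent(g_keep, "aaa", "bbb"))
  g_drop <- suppressMessages(
    build_graph(recs, c("ego1", "ego2"), min_df = 1,
                phi_threshold = weak_phi + 1e-9, min_cooccurrence = 1)
  )
  expect_true(igraph::are_adjacent(g_drop, "aaa", "ego1"))  # phi = 1 kept
  expect_false("bbb" %in% igraph::V(g_drop)$name)  # all its links below
  # at exactly the threshold the link is retained (phi >= threshold)
  g_eq <- suppressMessages(
    build_graph(recs, c("ego1", "ego2"), min_df = 1,
                phi_threshold = weak_phi, min_cooccurrence = 1)
  )
  expect_true(igraph::are_adjacent(g_eq, "aaa", "bbb"))
})

test_that("min_cooccurrence gates the pair support (a cell)", {
  texts <- c(rep("ego1 aaa", 9), rep("ego2 bbb", 10))
  g <- suppressMessages(
    build_graph(records_from_texts(texts), c("ego1", "ego2"), min_df = 1,
                phi_threshold = 0, min_cooccurrence = 10)
  )
  expect_false("aaa" %in% igraph::V(g)$name)  # only 9 co-occurrences
  expect_true(igraph::are_adjacent(g, "ego2", "bbb"))
})

test_that("louvain matches exhaustive modularity maximization on small graphs", {
  set.seed(31)
  for (i in 1:12) {
    n <- sample(3:8, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.3, 0.9))
    igraph::V(g)$name <- letters[seq_len(n)]
    igraph::V(g)$is_ego <- FALSE
    if (igraph::ecount(g) == 0) next
    igraph::E(g)$phi <- runif(igraph::ecount(g), 0.05, 1)
    part <- louvain_communities(g, seed = i)
    expect_equal(part$modularity,
                 brute_force_max_modularity(g, igraph::E(g)$phi),
                 tolerance = 1e-9)
    expect_gte(part$modularity, singleton_modularity(g) - 1e-12)
  }
})

test_that("two disconnected triangles form two communities", {
  g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
  igraph::E(g)$phi <- 0.5
  igraph::V(g)$is_ego <- FALSE
  part <- louvain_communities(g, seed = 1)
  expect_equal(part$n_communities, 2L)
  expect_length(unique(part$assignment[c("a", "b", "c")]), 1L)
  expect_length(unique(part$assignment[c("d", "e", "f")]), 1L)
  expect_equal(part$modularity,
               brute_force_max_modularity(g, igraph::E(g)$phi),
               tolerance = 1e-9)
})

test_that("an edgeless graph yields singletons with modularity zero", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- c("a", "b", "c")
  igraph::V(g)$is_ego <- FALSE
  part <- louvain_communities(g, seed = 1)
  expect_equal(part$n_communities, 3L)
  expect_equal(part$modularity, 0)
})

test_that("louvain is deterministic given the seed", {
  set.seed(55)
  g <- igraph::sample_gnp(30, 0.2)
  igraph::V(g)$name <- sprintf("t%02d", 1:30)
  igraph::V(g)$is_ego <- FALSE
  igraph::E(g)$phi <- runif(igraph::ecount(g), 0.05, 1)
  p1 <- louvain_communities(g, seed = 9)
  p2 <- louvain_communities(g, seed = 9)
  expect_identical(p1, p2)
})

test_that("degree_report orders nodes and accounts for every community", {
  texts <- c(rep("ego1 aaa bbb", 6), rep("ego2 ccc", 6))
  g <- suppressMessages(
    build_graph(records_from_texts(texts), c("ego1", "ego2"), min_df = 1,
                phi_threshold = 0, min_cooccurrence = 1)
  )
  part <- louvain_communities(g, seed = 2)
  rep_ <- degree_report(g, part)
  # ego1-aaa-bbb triangle (degree 2 each, tie broken by term) then the pair
  expect_equal(rep_$nodes$term[1], "aaa")
  expect_equal(rep_$nodes$degree[rep_$nodes$term == "ego1"], 2L)
  expect_equal(rep_$nodes$degree[rep_$nodes$term == "ego2"], 1L)
  expect_true(all(diff(rep_$nodes$degree) <= 0))
  expect_equal(sum(rep_$communities$size), igraph::vcount(g))
  expect_true(all(rep_$nodes$is_ego[rep_$nodes$term %in% c("ego1", "ego2")]))
})
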