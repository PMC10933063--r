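# Synthetic EMS corpus generator with known ground truth: planted term
# trajectories (hazardous / noteworthy / diffusion / flat signatures) and
# planted co-occurrence blocks recoverable by community detection.
#
# Documents are bags of tokens joined with single spaces, so the default
# tokenizer inverts generation exactly. A term's presence in a document is a
# Bernoulli draw; yearly rates follow the trajectory shape times a lognormal
# year effect (mean 1) that injects volatility without moving the mean rate.

#' Describe a planted term trajectory
#'
#' The trajectory kinds mirror the category signatures the pipeline should
#' recover: `hazardous` (high rate, rising, volatile), `noteworthy` (low
#' rate, rising, volatile), `diffusion` (high rate, declining, steady) and
#' `flat` (steady control).
#'
#' @param term Token (will appear verbatim in narratives).
#' @param kind Trajectory kind.
#' @param base_rate Expected documents per year containing the term, averaged
#'   over the study window. Defaults per kind assume the default corpus scale
#'   of 200 incidents/year: 60 (hazardous), 12 (noteworthy), 60 (diffusion),
#'   30 (flat).
#' @param slope Relative change in rate per year, centred on the window
#'   midpoint (so the mean rate stays `base_rate`). Defaults: +0.18
#'   (hazardous), +0.15 (noteworthy), -0.15 (diffusion), 0 (flat).
#' @param sigma SD (log scale) of the lognormal year effect. Defaults: 0.4
#'   for the volatile kinds, 0.08 otherwise.
#' @return A `planted_term` list.
#' @export
planted_term <- function(term,
                         kind = c("hazardous", "noteworthy", "diffusion",
                                  "flat"),
                         base_rate = NULL, slope = NULL, sigma = NULL) {
  kind <- match.arg(kind)
  defaults <- list(
    hazardous = list(base_rate = 60, slope = 0.18, sigma = 0.4),
    noteworthy = list(base_rate = 12, slope = 0.15, sigma = 0.4),
    diffusion = list(base_rate = 60, slope = -0.15, sigma = 0.08),
    flat = list(base_rate = 30, slope = 0, sigma = 0.08)
  )[[kind]]
  base_rate <- base_rate %||% defaults$base_rate
  slope <- slope %||% defaults$slope
  sigma <- sigma %||% defaults$sigma
  if (base_rate <= 0) rlang::abort("`base_rate` must be positive.")
  if (sigma < 0) rlang::abort("`sigma` must be >= 0.")
  if (kind == "hazardous" && slope <= 0) {
    rlang::abort("A hazardous trajectory must have a positive slope.")
  }
  if (kind == "noteworthy" && slope <= 0) {
    rlang::abort("A noteworthy trajectory must have a positive slope.")
  }
  if (kind == "diffusion" && slope > 0) {
    rlang::abort("A diffusion trajectory must have a non-positive slope.")
  }
  structure(list(term = as.character(term), kind = kind,
                 base_rate = base_rate, slope = slope, sigma = sigma),
            class = "planted_term")
}

#' Describe a planted co-occurrence block
#'
#' Terms of one block co-occur within documents at
#' `within_cooccurrence_prob`; terms of different blocks co-occur at
#' `between_cooccurrence_prob`. Realized by mixed membership: each document
#' is assigned to exactly one block; members of the assigned block are
#' present with probability `s`, members of other blocks leak in with
#' probability `v`, where `s` and `v` are solved from the two target
#' probabilities given the number of blocks (see the methods vignette).
#'
#' @param member_terms Character vector of block member tokens.
#' @param within_cooccurrence_prob Target probability that two members of
#'   this block co-occur in a random document (default 0.3).
#' @param between_cooccurrence_prob Target probability that a member of this
#'   block co-occurs with a member of another block (default 0.02).
#' @return A `planted_block` list.
#' @export
planted_block <- function(member_terms, within_cooccurrence_prob = 0.3,
                          between_cooccurrence_prob = 0.02) {
  if (length(member_terms) < 2L) {
    rlang::abort("A block needs at least 2 member terms.")
  }
  if (!(within_cooccurrence_prob > between_cooccurrence_prob)) {
    rlang::abort(
      "`within_cooccurrence_prob` must exceed `between_cooccurrence_prob`."
    )
  }
  if (within_cooccurrence_prob <= 0 || within_cooccurrence_prob >= 1 ||
      between_cooccurrence_prob < 0) {
    rlang::abort("Co-occurrence probabilities must lie in (0, 1).")
  }
  structure(list(member_terms = as.character(member_terms),
                 within = within_cooccurrence_prob,
                 between = between_cooccurrence_prob),
            class = "planted_block")
}

#' Specify a synthetic corpus
#'
#' @param n_years Number of study years (>= 3; acceleration needs at least
#'   two increments).
#' @param incidents_per_year Documents generated per year.
#' @param background_vocab_size Number of background filler terms
#'   (`bg0001`, `bg0002`, ...), with presence rates declining geometrically.
#' @param planted_terms List of [planted_term()] objects.
#' @param planted_blocks List of [planted_block()] objects.
#' @param doc_length_mean Expected number of background tokens per document
#'   (>= 2); planted and block tokens come on top.
#' @param start_year First calendar year of the window.
#' @param seed Integer seed; one seed drives the whole corpus, with per-year
#'   substreams derived from it.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_years = 10, incidents_per_year = 200,
                           background_vocab_size = 200,
                           planted_terms = list(), planted_blocks = list(),
                           doc_length_mean = 17, start_year = 2013,
                           seed = 1L) {
  if (!is_count(n_years, min = 3L)) {
    rlang::abort("Invalid spec: `n_years` must be a count >= 3.")
  }
  if (!is_count(incidents_per_year, min = 1L)) {
    rlang::abort("Invalid spec: `incidents_per_year` must be a count >= 1.")
  }
  if (!is_count(background_vocab_size, min = 0L)) {
    rlang::abort("Invalid spec: `background_vocab_size` must be a count >= 0.")
  }
  if (!is.numeric(doc_length_mean) || doc_length_mean < 2) {
    rlang::abort("Invalid spec: `doc_length_mean` must be >= 2.")
  }
  stopifnot(all(vapply(planted_terms, inherits, logical(1), "planted_term")),
            all(vapply(planted_blocks, inherits, logical(1), "planted_block")))
  pt_names <- vapply(planted_terms, `[[`, character(1), "term")
  blk_names <- unlist(lapply(planted_blocks, `[[`, "member_terms"))
  special <- c(pt_names, blk_names)
  if (anyDuplicated(special)) {
    rlang::abort("Invalid spec: planted term names must be unique.")
  }
  bg <- background_terms(background_vocab_size)
  if (any(special %in% bg)) {
    rlang::abort(
      "Invalid spec: planted terms must be disjoint from background vocabulary."
    )
  }
  structure(
    list(n_years = as.integer(n_years),
         incidents_per_year = as.integer(incidents_per_year),
         background_vocab_size = as.integer(background_vocab_size),
         planted_terms = planted_terms, planted_blocks = planted_blocks,
         doc_length_mean = doc_length_mean,
         start_year = as.integer(start_year), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

background_terms <- function(v) {
  if (v == 0L) return(character())
  sprintf("bg%04d", seq_len(v))
}

# Background presence rates: geometric decline from 0.14 to 0.05 of
# documents, rescaled so their sum equals doc_length_mean.
background_rates <- function(v, doc_length_mean) {
  if (v == 0L) return(numeric())
  q <- 0.14 * (0.05 / 0.14)^((seq_len(v) - 1) / max(v - 1, 1))
  clamp(q * doc_length_mean / sum(q), 0, 0.95)
}

# Yearly presence probabilities (per document) of one planted term.
planted_rate_curve <- function(pt, n_years, incidents_per_year) {
  y <- seq_len(n_years) - (n_years + 1) / 2  # centred year index
  rate <- pt$base_rate * (1 + pt$slope * y)
  clamp(rate / incidents_per_year, 0, 0.95)
}

# Solve the per-document presence probabilities (s within the assigned
# block, v leak otherwise) hitting the block's co-occurrence targets given
# n_blocks. Fixed-point iteration on:
#   within  = s^2/B + (B-1) v^2 / B
#   between = (2 s v + (B-2) v^2) / B
solve_block_probs <- function(within, between, n_blocks) {
  b <- n_blocks
  if (b == 1L) {
    s <- sqrt(within)
    if (s > 1) rlang::abort("Infeasible within_cooccurrence_prob.")
    return(list(s = s, v = 0))
  }
  v <- 0
  s <- sqrt(within * b)
  for (it in 1:50) {
    s2 <- within * b - (b - 1) * v^2
    if (s2 <= 0) rlang::abort("Infeasible block co-occurrence targets.")
    s <- sqrt(s2)
    # 2 s v + (b - 2) v^2 = b * between, solve quadratic in v
    if (b == 2L) {
      v <- b * between / (2 * s)
    } else {
      v <- (-2 * s + sqrt(4 * s^2 + 4 * (b - 2) * b * between)) /
        (2 * (b - 2))
    }
  }
  if (s > 1 || v < 0 || v > 1) {
    rlang::abort("Infeasible block co-occurrence targets.")
  }
  list(s = s, v = v)
}

#' Generate a synthetic corpus
#'
#' Deterministic given the spec's seed: per-year substream seeds are drawn
#' once from the global seed, then each year's documents are sampled
#' independently. Narratives are the sampled tokens in randomized order,
#' joined with single spaces.
#'
#' @param spec A [synthetic_spec()].
#' @return Incident records tibble (`id`, `year`, `text`) with
#'   `n_years * incidents_per_year` rows.
#' @export
generate_corpus <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    rlang::abort("`spec` must be a synthetic_spec.")
  }
  ny <- spec$n_years
  ipy <- spec$incidents_per_year
  bg <- background_terms(spec$background_vocab_size)
  bg_q <- background_rates(spec$background_vocab_size, spec$doc_length_mean)
  nb <- length(spec$planted_blocks)
  blk_probs <- lapply(spec$planted_blocks, function(b) {
    solve_block_probs(b$within, b$between, nb)
  })

  year_seeds <- with_local_seed(spec$seed, {
    sample.int(.Machine$integer.max, ny)
  })

  years <- spec$start_year + seq_len(ny) - 1L
  rec_list <- vector("list", ny)
  for (yi in seq_len(ny)) {
    rec_list[[yi]] <- with_local_seed(year_seeds[yi], {
      # per-term presence probability this year
      p_planted <- vapply(spec$planted_terms, function(pt) {
        eff <- exp(rnorm(1, 0, pt$sigma) - pt$sigma^2 / 2)
        clamp(planted_rate_curve(pt, ny, ipy)[yi] * eff, 0, 0.95)
      }, numeric(1))
      pt_names <- vapply(spec$planted_terms, `[[`, character(1), "term")

      present <- matrix(FALSE, nrow = ipy, ncol = 0)
      cols <- character()
      if (length(pt_names)) {
        m <- vapply(p_planted, function(p) rbinom(ipy, 1L, p) == 1L,
                    logical(ipy))
        present <- cbind(present, matrix(m, nrow = ipy))
        cols <- c(cols, pt_names)
      }
      if (length(bg)) {
        m <- vapply(bg_q, function(p) rbinom(ipy, 1L, p) == 1L, logical(ipy))
        present <- cbind(present, matrix(m, nrow = ipy))
        cols <- c(cols, bg)
      }
      if (nb > 0L) {
        assignment <- sample.int(nb, ipy, replace = TRUE)
        for (bi in seq_len(nb)) {
          blk <- spec$planted_blocks[[bi]]
          pr <- blk_probs[[bi]]
          p <- ifelse(assignment == bi, pr$s, pr$v)
          m <- vapply(seq_along(blk$member_terms), function(k) {
            rbinom(ipy, 1L, p) == 1L
          }, logical(ipy))
          present <- cbind(present, matrix(m, nrow = ipy))
          cols <- c(cols, blk$member_terms)
        }
      }
      colnames(present) <- cols

      texts <- vapply(seq_len(ipy), function(dd) {
        tk <- cols[present[dd, ]]
        if (length(tk) == 0L) tk <- bg[1]  # never emit an empty narrative
        paste(sample(tk), collapse = " ")
      }, character(1))
      tibble::tibble(
        id = sprintf("Y%d-%05d", years[yi], seq_len(ipy)),
        year = years[yi],
        text = texts
      )
    })
  }
  dplyr::bind_rows(rec_list)
}

#' Ground-truth categories of a synthetic spec
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble `term`, `category` covering the planted trajectory terms
#'   (`flat` maps to `"unclassified"`). Background and block terms are
#'   unclassified by construction and are omitted.
#' @export
ground_truth <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    rlang::abort("`spec` must be a synthetic_spec.")
  }
  if (length(spec$planted_terms) == 0L) {
    return(tibble::tibble(term = character(), category = character()))
  }
  tibble::tibble(
    term = vapply(spec$planted_terms, `[[`, character(1), "term"),
    category = vapply(spec$planted_terms, function(pt) {
      if (pt$kind == "flat") "unclassified" else pt$kind
    }, character(1))
  )
}

#' Ground-truth block membership of a synthetic spec
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble `term`, `block` (1-based block index).
#' @export
block_truth <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    rlang::abort("`spec` must be a synthetic_spec.")
  }
  dplyr::bind_rows(lapply(seq_along(spec$planted_blocks), function(bi) {
    tibble::tibble(term = spec$planted_blocks[[bi]]$member_terms, block = bi)
  }))
}

#' Default study-condition spec with planted categories and blocks
#'
#' Convenience constructor for the validation corpus used throughout the
#' test-suite: `n_per_kind` planted terms of each trajectory kind and three
#' 6-term co-occurrence blocks.
#'
#' @param n_per_kind Planted terms per trajectory kind (default 30).
#' @param seed Integer seed.
#' @param ... Passed on to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
default_validation_spec <- function(n_per_kind = 30L, seed = 1L, ...) {
  kinds <- c("hazardous", "noteworthy", "diffusion")
  pts <- unlist(lapply(kinds, function(k) {
    lapply(seq_len(n_per_kind), function(i) {
      planted_term(sprintf("%s%02d", substr(k, 1, 3), i), kind = k)
    })
  }), recursive = FALSE)
  blocks <- lapply(1:3, function(bi) {
    planted_block(sprintf("blk%d_%02d", bi, 1:6))
  })
  synthetic_spec(planted_terms = pts, planted_blocks = blocks, seed = seed,
                 ...)
}
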