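test_that("average_frequency zero-fills over the study window", {
  expect_equal(average_frequency(c(10, 10, 10)), 10)
  expect_equal(average_frequency(c(0, 0, 30)), 10)
  expect_equal(average_frequency(5, n_years = 10), 0.5)
})

test_that("average_acceleration is the mean yearly increment up to last use", {
  expect_equal(as.numeric(average_acceleration(c(10, 10, 10, 10))), 0)
  expect_equal(as.numeric(average_acceleration(c(10, 20, 30, 40))), 10)
  expect_equal(as.numeric(average_acceleration(c(40, 30, 20, 10))), -10)
  # trailing zeros: accumulate only until the last appearance
  expect_equal(as.numeric(average_acceleration(c(10, 20, 30, 0, 0))), 10)
  # degenerate spans flagged and zero
  a <- average_acceleration(c(5, 0, 0))
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "undefined"))
  expect_true(attr(average_acceleration(c(0, 0, 0)), "undefined"))
})

test_that("average_acceleration is antisymmetric under time reversal", {
  set.seed(21)
  for (i in 1:25) {
    f <- c(sample(1:50, 1), sample(0:50, 6, replace = TRUE),
           sample(1:50, 1))  # non-zero endpoints keep the span full
    expect_equal(as.numeric(average_acceleration(rev(f))),
                 -as.numeric(average_acceleration(f)))
  }
})

test_that("second-difference acceleration variant is available", {
  expect_equal(
    as.numeric(average_acceleration(c(1, 2, 4, 8), "second_difference")),
    mean(diff(diff(c(1, 2, 4, 8))))
  )
  expect_equal(
    as.numeric(average_acceleration(c(10, 20, 30, 40), "second_difference")),
    0
  )
})

test_that("relative_volatility is the SD ratio against the pooled mean SD", {
  expect_equal(relative_volatility(c(7, 7, 7), all_sds = c(1, 2, 3)), 0)
  expect_equal(relative_volatility(c(0, 10), all_sds = c(5, 5, 5)), 1)
  expect_equal(relative_volatility(c(0, 10), all_sds = c(2.5, 2.5)), 2)
  expect_equal(trajectory_sd(c(0, 10)), 5)                     # population
  expect_equal(trajectory_sd(c(0, 10), "sample"), sd(c(0, 10)))
  expect_error(relative_volatility(c(1, 2), all_sds = c(0, 0)), "Degenerate")
})

test_that("relative_volatility ignores a constant shift of every term", {
  set.seed(4)
  mat <- matrix(sample(0:30, 50, replace = TRUE), nrow = 10)
  sds <- apply(mat, 1, trajectory_sd)
  sds_shift <- apply(mat + 7, 1, trajectory_sd)
  for (i in 1:10) {
    expect_equal(relative_volatility(mat[i, ] + 7, sds_shift),
                 relative_volatility(mat[i, ], sds))
  }
})

test_that("rank_scores bands by percentile rank into quintiles", {
  set.seed(9)
  v100 <- sample(1:100)
  expect_equal(as.vector(table(rank_scores(v100))), rep(20L, 5))
  expect_equal(rank_scores(1:10), rep(1:5, each = 2))
  expect_equal(rank_scores(rep(3.3, 8)), rep(3L, 8))  # all-equal -> mid band
  expect_equal(rank_scores(1:10, higher_is_better = FALSE),
               rev(rep(1:5, each = 2)))
  expect_error(rank_scores(1:4), "at least 5")
})

test_that("apply_stoplist flags terms with their class", {
  sl <- list(time = c("morning", "afternoon"), person = "acquaintance",
             body_site = c("wrist", "legs"))
  got <- apply_stoplist(c("morning", "fall", "wrist"), sl)
  expect_equal(got$excluded, c(TRUE, FALSE, TRUE))
  expect_equal(got$excluded_reason, c("time", NA, "body_site"))
  none <- apply_stoplist(c("fall", "burn"), NULL)
  expect_false(any(none$excluded))
})

test_that("category rules match their defining score profiles", {
  expect_equal(categorize_scores(5, 4, 4), "hazardous")
  expect_equal(categorize_scores(2, 3, 3), "noteworthy")
  expect_equal(categorize_scores(5, 2, 1), "diffusion")
  expect_equal(categorize_scores(3, 3, 3), "unclassified")
  expect_error(categorize_scores(0, 3, 3), "1..5")
  expect_error(categorize_scores(3, 6, 3), "1..5")
})

test_that("category rules are mutually exclusive over all 125 triples", {
  grid <- expand.grid(f = 1:5, a = 1:5, v = 1:5)
  fires <- with(grid, cbind(
    hazardous = f >= 4 & a >= 4 & v >= 4,
    noteworthy = f <= 2 & a >= 3 & v >= 3,
    diffusion = f >= 4 & a <= 2
  ))
  expect_true(all(rowSums(fires) <= 1))
  got <- categorize_scores(grid$f, grid$a, grid$v)
  # the vectorized implementation agrees with the rule table everywhere
  expected <- rep("unclassified", nrow(grid))
  expected[fires[, "hazardous"]] <- "hazardous"
  expected[fires[, "noteworthy"]] <- "noteworthy"
  expected[fires[, "diffusion"]] <- "diffusion"
  expect_equal(got, expected)
})

test_that("assess_keywords scores before exclusion and drops categories after", {
  years <- 2013:2022
  mk <- function(term, f) tibble::tibble(term = term, year = years, df = f)
  traj <- dplyr::bind_rows(
    mk("rising", (1:10) * 10),
    mk("falling", (10:1) * 10),
    mk("steady", rep(50, 10)),
    mk("spiky", c(0, 0, 80, 0, 0, 90, 0, 0, 0, 100)),
    mk("morning", (1:10) * 12),
    mk("rare", c(rep(0, 8), 4, 6))
  )
  out <- assess_keywords(traj, years,
                         stoplist = list(time = "morning"))
  expect_setequal(names(out)[1:4],
                  c("term", "avg_freq", "avg_accel", "rel_volatility"))
  expect_equal(out$avg_accel[out$term == "rising"], 10)
  expect_equal(out$avg_accel[out$term == "falling"], -10)
  expect_true(out$excluded[out$term == "morning"])
  expect_true(is.na(out$category[out$term == "morning"]))
  # scores are still banded for excluded terms (exclusion happens afterwards)
  expect_true(out$score_freq[out$term == "morning"] %in% 1:5)
  kept <- out[!out$excluded, ]
  expect_true(all(kept$category %in%
                    c("hazardous", "noteworthy", "diffusion", "unclassified")))
})

test_that("category_summary aggregates per assigned category", {
  years <- 2013:2022
  mk <- function(term, f) tibble::tibble(term = term, year = years, df = f)
  traj <- dplyr::bind_rows(
    mk("t1", (1:10) * 10), mk("t2", (10:1) * 10), mk("t3", rep(50, 10)),
    mk("t4", c(1:9, 0)), mk("t5", rep(c(10, 60), 5))
  )
  out <- assess_keywords(traj, years)
  summ <- category_summary(out)
  expect_equal(sum(summ$n), sum(!out$excluded & !is.na(out$category)))
  expect_true(all(c("mean_avg_freq", "representative") %in% names(summ)))
})
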