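test_that("log_fold_change applies the prior count", {
  expect_equal(log_fold_change(4, 4, 1), 0)
  expect_equal(log_fold_change(1, 7, 1), 2)
  expect_equal(log_fold_change(0, 15, 1), 4)  # log2(16/1)
  expect_equal(log_fold_change(c(1, 0), c(7, 15), 1), c(2, 4))
  expect_error(log_fold_change(0, 5, 0), "undefined")
  expect_error(log_fold_change(-1, 5, 1), "nonnegative")
})

test_that("comparison_rank_scores ranks fold changes and assigns virtual scores", {
  m <- matrix(c(2, 16, 8, 8, 16, 2, 0, 9, 9, 0, 0, 0), ncol = 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:6), c("s1", "s2")))
  sc <- comparison_rank_scores(m, "s1", "s2", sigma0 = 0.1, n0 = 1)
  expect_equal(attr(sc, "omega"), 3)
  expect_equal(unname(sc[1:3]), (c(1, 2, 3) - 0.5) / 3)
  expect_equal(unname(sc["g4"]), 0.1)      # zero -> positive
  expect_equal(unname(sc["g5"]), 0.9)      # positive -> zero
  expect_true(is.na(sc["g6"]))             # both zero: undefined

  # single both-positive gene sits at the midpoint
  m1 <- matrix(c(3, 5, 0, 0), ncol = 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(comparison_rank_scores(m1, "s1", "s2")["g1"]), 0.5)

  expect_error(comparison_rank_scores(m, "s1", "nope"), "unknown sample")
  expect_error(comparison_rank_scores(m, "s1", "s2", sigma0 = 0.7),
               "between 0 and 0.5")
  expect_error(comparison_rank_scores(m, "s1", "s2", sigma0 = 0.5),
               "between 0 and 0.5")
})

test_that("rank scores are symmetric: extremes 0.5/Omega and mean exactly 0.5", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_counts(40, 2, zero_prob = 0.2)
    sc <- comparison_rank_scores(m, "s1", "s2")
    omega <- attr(sc, "omega")
    both <- m[, 1] > 0 & m[, 2] > 0
    if (omega == 0) next
    bp <- sc[both]
    expect_equal(mean(bp), 0.5)
    expect_gte(min(bp), 0.5 / omega)
    expect_lte(max(bp), 1 - 0.5 / omega)
    expect_true(all(bp > 0 & bp < 1))
  }
})

test_that("reversing a comparison maps scores to their complement", {
  set.seed(22)
  for (i in 1:10) {
    m <- random_counts(30, 2, zero_prob = 0.25)
    fwd <- comparison_rank_scores(m, "s1", "s2")
    rev <- comparison_rank_scores(m, "s2", "s1")
    both <- !is.na(fwd)
    expect_equal(unname(rev[both]), 1 - unname(fwd[both]))
    expect_identical(is.na(rev), is.na(fwd))
  }
})

test_that("larger fold change strictly implies smaller score (absent ties)", {
  set.seed(23)
  m <- random_counts(50, 2, zero_prob = 0)
  m <- m + 1  # strictly positive
  x <- log_fold_change(m[, 1], m[, 2], 1)
  sc <- comparison_rank_scores(m, "s1", "s2")
  untied <- !(x %in% x[duplicated(x)])
  ord <- order(x[untied])
  expect_true(all(diff(sc[untied][ord]) < 0))
})

test_that("ranking is invariant to per-sample scaling at n0 = 0", {
  set.seed(24)
  # continuous counts: no fold-change ties, which scaling could re-round
  m <- matrix(exp(rnorm(120, 7.7, 1.3)), 30, 4,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:4)))
  d <- comparison_design(list(rbind(c("s1", "s2"), c("s3", "s4"))))
  base <- rank_score_table(m, d, n0 = 0)
  m2 <- m
  m2[, "s2"] <- m2[, "s2"] * 7.3
  m2[, "s3"] <- m2[, "s3"] * 0.2
  scaled <- rank_score_table(m2, d, n0 = 0)
  expect_equal(unclass(base)[, ], unclass(scaled)[, ], tolerance = 1e-12)
})

test_that("aggregate_score multiplies negative log scores, skipping NA", {
  expect_equal(aggregate_score(c(1e-4, 1 - 1e-4)),
               -log(1e-4) * -log(1 - 1e-4))
  expect_equal(aggregate_score(c(1e-2, 1e-2)), log(100)^2)
  expect_equal(aggregate_score(exp(-1)), 1)
  expect_equal(aggregate_score(c(0.2, NA, 0.3)),
               -log(0.2) * -log(0.3))
  # direction -1 flips scores to their complement
  expect_equal(aggregate_score(c(0.9, 0.8), d = -1),
               -log(0.1) * -log(0.2))
  # per-group directions
  expect_equal(aggregate_score(c(0.1, 0.9), d = c(1, -1), groups = c(1, 2)),
               log(10)^2)
  expect_error(aggregate_score(c(NA_real_, NA_real_)), "no defined")
  expect_error(aggregate_score(0.2, d = 2), "\\+1 or -1")
  expect_error(aggregate_score(c(0.2, 0.3), d = 1, groups = c(1, 2)),
               "shorter")
})

test_that("consistent extremes outrank alternating extremes and midpoints", {
  # k consistent extreme scores beat alternating extreme directions
  k <- 4
  consistent <- aggregate_score(rep(1e-3, k))
  alternating <- aggregate_score(rep(c(1e-3, 1 - 1e-3), k / 2))
  expect_gt(consistent, alternating)
  # and beat the all-midpoint gene under every direction
  mid <- aggregate_score(rep(0.5, k))
  expect_gt(consistent, mid)
  expect_equal(mid, log(2)^k)
})

test_that("rank_genes orders by best aggregate over all direction assignments", {
  m <- matrix(c(2, 16, 8, 8, 16, 2, 0, 9, 9, 0, 0, 0), ncol = 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:6), c("s1", "s2")))
  d <- single_group_design("s1", "s2")
  r <- rank_genes(m, d)
  # N = 1: final score is max of the two directions
  tab <- r$score_table
  for (g in setdiff(rownames(m), "g6")) {
    s <- tab[g, 1]
    expect_equal(r$ranking$score[r$ranking$gene_id == g],
                 max(-log(s), -log(1 - s)))
  }
  expect_identical(r$excluded, "g6")
  expect_identical(r$ranking$rank, 1:5)
  expect_true(all(diff(r$ranking$score) <= 0))
  # direction string marks the winning side
  expect_identical(r$ranking$directions[r$ranking$gene_id == "g5"], "-")
  expect_identical(r$ranking$directions[r$ranking$gene_id == "g4"], "+")
})

test_that("equal final scores break ties by input row order", {
  # g1 and g2 carry identical counts, so their fold changes tie, their
  # (tie-averaged) rank scores coincide, and their final scores are equal
  m <- matrix(c(2, 16, 2, 16, 4, 4), ncol = 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  r <- rank_genes(m, single_group_design("s1", "s2"))
  tied <- r$ranking[r$ranking$gene_id %in% c("g1", "g2"), ]
  expect_identical(tied$score[1], tied$score[2])
  expect_identical(tied$gene_id[order(tied$rank)], c("g1", "g2"))
})

test_that("direction_combine = min keeps the worst assignment", {
  m <- matrix(c(2, 16, 8, 8, 16, 2), ncol = 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  d <- single_group_design("s1", "s2")
  rmin <- rank_genes(m, d, direction_combine = "min")
  tab <- rmin$score_table
  for (g in rownames(m)) {
    s <- tab[g, 1]
    expect_equal(rmin$ranking$score[rmin$ranking$gene_id == g],
                 min(-log(s), -log(1 - s)))
  }
})

test_that("rank_genes matches the brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:40) {
    m <- random_counts(8, 4, zero_prob = 0.3)
    m <- filter_all_zero_rows(m)$counts
    if (nrow(m) == 0) next
    d <- if (i %% 2 == 0) {
      comparison_design(list(rbind(c("s1", "s2"), c("s3", "s4"))))
    } else {
      comparison_design(list(rbind(c("s1", "s2")), rbind(c("s3", "s4"))))
    }
    got <- rank_genes(m, d)
    want <- oracle_rank(m, d)
    expect_equal(got$ranking$score, want$ranking$score, tolerance = 1e-12)
    expect_identical(got$ranking$gene_id, want$ranking$gene_id)
    expect_identical(got$ranking$directions, want$ranking$directions)
    expect_identical(got$excluded, want$excluded)
  }
})
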