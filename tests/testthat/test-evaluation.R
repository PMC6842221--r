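test_that("precision_recall computes exact set ratios", {
  expect_equal(precision_recall(c("a", "b"), c("a", "b")),
               c(precision = 1, recall = 1))
  expect_equal(precision_recall(c("x", "y"), c("a", "b")),
               c(precision = 0, recall = 0))
  expect_equal(precision_recall(c("a", "b", "c", "d"), c("a", "b", "e")),
               c(precision = 0.5, recall = 2 / 3))
  # empty found set: precision undefined, recall zero
  pr <- precision_recall(character(0), c("a", "b"))
  expect_true(is.na(pr["precision"]))
  expect_equal(unname(pr["recall"]), 0)
  expect_error(precision_recall(c("a"), character(0)), "non-empty")
})

test_that("precision_recall is invariant under relabeling gene ids", {
  set.seed(71)
  ids <- paste0("g", 1:50)
  found <- sample(ids, 20)
  ref <- sample(ids, 15)
  relabel <- setNames(paste0("x", seq_along(ids)), ids)
  expect_equal(precision_recall(found, ref),
               precision_recall(unname(relabel[found]),
                                unname(relabel[ref])))
})

test_that("ranking_curves hits the analytic boundary cases", {
  ranking <- paste0("g", 1:10)
  # all positives first
  c1 <- ranking_curves(ranking, c("g1", "g2", "g3"))
  expect_equal(c1$auc_roc, 1)
  expect_equal(c1$auc_pr, 1)
  # single positive ranked last
  c2 <- ranking_curves(ranking, "g10")
  expect_equal(c2$auc_roc, 0)
  # perfectly interleaved worst-for-pr boundary values stay in [0, 1]
  expect_true(c2$auc_pr >= 0 && c2$auc_pr <= 1)
  expect_error(ranking_curves(ranking, "absent"), "disjoint")
  expect_error(ranking_curves(c("g1", "g1"), "g1"), "duplicate")
})

test_that("random rankings give ROC area near one half", {
  set.seed(72)
  ids <- paste0("g", 1:60)
  pos <- paste0("g", 1:12)
  aucs <- replicate(100, ranking_curves(sample(ids), pos)$auc_roc)
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
})

test_that("PR area equals the brute-force average precision at positives", {
  set.seed(73)
  for (i in 1:10) {
    ids <- paste0("g", 1:25)
    ranking <- sample(ids)
    pos <- sample(ids, 6)
    got <- ranking_curves(ranking, pos)$auc_pr
    # independent small-instance oracle
    want <- 0
    for (p in pos) {
      k <- match(p, ranking)
      want <- want + sum(ranking[1:k] %in% pos) / k
    }
    expect_equal(got, want / length(pos))
  }
})

test_that("zero_fraction_of counts zeros over the selected cells", {
  m <- matrix(c(0, 5, 10, 0, 3, 4), ncol = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expect_equal(zero_fraction_of(m, c("g1", "g2")), 0.5)
  expect_equal(zero_fraction_of(m, "g3"), 0)
  expect_equal(zero_fraction_of(m, c("g1", "g2"), "s1"), 0.5)
  z <- matrix(0, 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_equal(zero_fraction_of(z, "g1"), 1)
  expect_error(zero_fraction_of(m, character(0)), "non-empty")
  expect_error(zero_fraction_of(m, "nope"), "unknown gene")
})

test_that("relative_representation fractions sum to one and detect bias", {
  set.seed(74)
  m <- matrix(exp(rnorm(2000, 7.7, 1.3)), ncol = 4,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  # the full gene set is its own reference: every occupied bin has ratio 1
  rr_all <- relative_representation(m, rownames(m))
  occ <- rr_all$f0 > 0
  expect_equal(rr_all$ratio[occ], rep(1, sum(occ)))
  expect_equal(sum(rr_all$f0), 1)
  expect_equal(sum(rr_all$f_de), 1)
  expect_true(all(is.na(rr_all$ratio[!occ])))

  # a DE set concentrated in the top-count decile inflates the top bins
  med <- apply(m, 1, stats::median)
  top <- names(sort(med, decreasing = TRUE))[1:50]
  rr_top <- relative_representation(m, top)
  hi <- rr_top$bin >= 9 & rr_top$f0 > 0
  lo <- rr_top$bin <= 5 & rr_top$f0 > 0
  expect_true(all(rr_top$ratio[hi] > 1, na.rm = TRUE))
  expect_true(all(rr_top$ratio[lo] < 1, na.rm = TRUE))

  # uniformly sampled DE genes have ratios near 1
  unif <- sample(rownames(m), 250)
  rr_u <- relative_representation(m, unif)
  expect_equal(mean(abs(rr_u$ratio[rr_u$f0 > 0.02] - 1) < 0.5), 1)

  expect_error(relative_representation(m, character(0)), "non-empty")
})

test_that("plot helpers run headless without error", {
  sim <- simulate_counts(n_genes = 80, de_fraction = 0.1, seed = 75)
  rk <- rank_genes(filter_all_zero_rows(sim$counts)$counts, sim$design)
  f <- estimate_fdr(rk, n_boot = 10, seed = 76)
  path <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(path)
  expect_no_error(plot_rank_scores(f, top = 40))
  cv <- ranking_curves(rk$ranking$gene_id, sim$truth$gene_id[sim$truth$is_de])
  expect_no_error(plot_curves(cv))
  grDevices::dev.off()
  expect_true(file.exists(path))
})
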