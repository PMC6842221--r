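# Nonparametric bootstrap significance: per-comparison permutation of rank
# scores, expected counts of better-scoring genes, monotone FDR.

#' One bootstrap realization of a rank-score table
#'
#' Independently for each comparison column, permutes the defined rank
#' scores (including virtual scores from zero-involving pairs) uniformly
#' among the genes that have a defined score in that column. The undefined
#' (both-zero) pattern is left untouched, so each column's multiset of
#' defined scores is preserved exactly.
#'
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param tab A [rank_score_table()] (or any numeric matrix with `NA` for
#'   undefined entries).
#' @return A matrix of the same shape and attributes with each column's
#'   defined entries permuted.
#' @export
bootstrap_realization <- function(tab) {
  out <- tab
  for (j in seq_len(ncol(out))) {
    idx <- which(!is.na(out[, j]))
    if (length(idx) > 1)
      out[idx, j] <- out[idx[sample.int(length(idx))], j]
  }
  out
}

#' Bootstrap false discovery rate for a gene ranking
#'
#' Creates `n_boot` simulated score tables by per-comparison permutation of
#' the observed rank scores ([bootstrap_realization()]), recomputes final
#' aggregate scores in each (re-optimising the direction assignment, so the
#' null accounts for direction selection), and counts for every real gene
#' the simulated genes that score strictly higher than its real final score.
#' With `N_g` the mean such count over realizations and `r_g` the gene's
#' real rank, the raw FDR estimate is `N_g / r_g` (capped at 1). A monotone
#' correction then propagates each gene's FDR down the ranking with
#' a running maximum, so the estimate never decreases with rank.
#'
#' @param ranking A [rank_genes()] result.
#' @param n_boot Number of bootstrap realizations, default 100.
#' @param seed Optional integer seed; per-realization child seeds are
#'   derived from it deterministically.
#' @return An object of class `protrank_fdr`: list with
#'   * `table`: data.frame `gene_id`, `rank`, `score`, `n_better` (N_g),
#'     `fdr_raw`, `fdr` (monotone-corrected);
#'   * `n_boot`; `boot_scores`: matrix of sorted (decreasing) final scores,
#'     one column per realization, for rank-plot diagnostics.
#' @export
estimate_fdr <- function(ranking, n_boot = 100, seed = NULL) {
  stopifnot(inherits(ranking, "protrank_ranking"))
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 1)
    stop("n_boot must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max, n_boot)

  tab <- ranking$score_table
  group <- attr(tab, "group")
  dirs <- enumerate_directions(n_groups(ranking$design))
  rankable <- rownames(tab) %in% ranking$ranking$gene_id
  real_score <- ranking$ranking$score          # decreasing in rank
  G <- sum(rankable)

  n_better <- numeric(nrow(ranking$ranking))
  boot_scores <- matrix(NA_real_, G, n_boot)
  for (i in seq_len(n_boot)) {
    set.seed(child_seeds[i])
    bt <- bootstrap_realization(tab)
    agg <- aggregate_all(bt[rankable, , drop = FALSE], group, dirs,
                         ranking$direction_combine)
    s <- sort(agg$score)                        # ascending
    # strictly greater: total minus count of boot scores <= real score
    n_better <- n_better + (G - findInterval(real_score, s))
    boot_scores[, i] <- rev(s)
  }
  n_better <- n_better / n_boot
  raw <- pmin(n_better / ranking$ranking$rank, 1)
  structure(list(
    table = data.frame(gene_id = ranking$ranking$gene_id,
                       rank = ranking$ranking$rank,
                       score = real_score,
                       n_better = n_better,
                       fdr_raw = raw,
                       fdr = cummax(raw),
                       stringsAsFactors = FALSE, row.names = NULL),
    n_boot = n_boot,
    boot_scores = boot_scores
  ), class = "protrank_fdr")
}

#' Significant genes at an FDR threshold
#'
#' @param fdr A [estimate_fdr()] result.
#' @param threshold FDR level in (0, 1], default 0.20.
#' @return Character vector of gene ids with corrected FDR below the
#'   threshold, in rank order.
#' @export
significant_genes <- function(fdr, threshold = 0.20) {
  stopifnot(inherits(fdr, "protrank_fdr"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  fdr$table$gene_id[fdr$table$fdr < threshold]
}

#' @export
print.protrank_fdr <- function(x, ...) {
  cat(sprintf("bootstrap FDR: %d gene(s), %d realization(s)\n",
              nrow(x$table), x$n_boot))
  cat(sprintf("  genes with FDR < 0.20: %d\n", sum(x$table$fdr < 0.20)))
  print(utils::head(x$table))
  invisible(x)
}
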