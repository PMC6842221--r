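# Core ranking engine: per-comparison rank scores, virtual scores for
# zero-involving comparisons, and direction-aware aggregation.

#' Log2 fold change with a prior count
#'
#' Computes `log2((n_after + n0) / (n_before + n0))`. The prior count
#' (pseudocount) shrinks fold changes at low counts towards zero; the
#' package default downstream is `n0 = 1`.
#'
#' @param n_before,n_after Nonnegative counts (vectorised).
#' @param n0 Prior count added to both counts, default 1.
#' @return Numeric vector of log2 fold changes.
#' @examples
#' log_fold_change(1, 7, 1)   # log2(8/2) = 2
#' @export
log_fold_change <- function(n_before, n_after, n0 = 1) {
  if (any(n_before < 0) || any(n_after < 0) || n0 < 0)
    stop("counts and prior count must be nonnegative", call. = FALSE)
  if (any(n_before + n0 == 0) || any(n_after + n0 == 0))
    stop("log fold change undefined: zero count with zero prior count",
         call. = FALSE)
  log2((n_after + n0) / (n_before + n0))
}

#' Rank scores for a single comparison
#'
#' For the Omega genes with positive counts in both samples, log2 fold
#' changes are ranked from the largest (rank 1) to the smallest (rank Omega)
#' with average ranks for ties, then rescaled to
#' `sigma = (rank - 0.5) / Omega`, which is symmetric in (0, 1). Genes going
#' from zero to a positive count receive the fixed virtual score `sigma0`
#' (a strong-upregulation score); positive to zero receives `1 - sigma0`;
#' genes with both counts zero are undefined (`NA`).
#'
#' @param m Count matrix.
#' @param before,after Sample ids of the compared columns.
#' @param sigma0 Virtual rank score for zero -> positive changes, in
#'   (0, 0.5); default 0.1.
#' @param n0 Prior count, default 1.
#' @return Numeric vector of scores (named by gene), `NA` for both-zero
#'   pairs, with attribute `omega` (number of both-positive genes).
#' @export
comparison_rank_scores <- function(m, before, after, sigma0 = 0.1, n0 = 1) {
  validate_counts(m)
  check_sigma0(sigma0)
  miss <- setdiff(c(before, after), colnames(m))
  if (length(miss) > 0)
    stop("unknown sample(s): ", paste(miss, collapse = ", "), call. = FALSE)
  b <- m[, before]
  a <- m[, after]
  sc <- rep(NA_real_, nrow(m))
  names(sc) <- rownames(m)
  both <- b > 0 & a > 0
  omega <- sum(both)
  if (omega > 0) {
    x <- log_fold_change(b[both], a[both], n0)
    r <- rank(-x, ties.method = "average")
    sc[both] <- (r - 0.5) / omega
  }
  sc[b == 0 & a > 0] <- sigma0
  sc[b > 0 & a == 0] <- 1 - sigma0
  attr(sc, "omega") <- omega
  sc
}

check_sigma0 <- function(sigma0) {
  if (!is.numeric(sigma0) || length(sigma0) != 1 ||
      sigma0 <= 0 || sigma0 >= 0.5)
    stop("sigma0 must lie strictly between 0 and 0.5", call. = FALSE)
  invisible(sigma0)
}

#' Rank-score table over a full design
#'
#' Applies [comparison_rank_scores()] to every designed comparison.
#'
#' @param m Count matrix.
#' @param design A [comparison_design()].
#' @param sigma0,n0 See [comparison_rank_scores()].
#' @return A genes x comparisons numeric matrix of class `rank_score_table`
#'   with `NA` for both-zero pairs and attributes `omega` (per-comparison
#'   both-positive counts), `group` (integer group index per column),
#'   `sigma0`, `n0`.
#' @export
rank_score_table <- function(m, design, sigma0 = 0.1, n0 = 1) {
  comps <- design_comparisons(design)
  cols <- lapply(seq_len(nrow(comps)), function(k)
    comparison_rank_scores(m, comps$before[k], comps$after[k], sigma0, n0))
  tab <- do.call(cbind, lapply(cols, as.numeric))
  dimnames(tab) <- list(rownames(m),
                        paste0(comps$before, "->", comps$after))
  structure(tab,
            omega = vapply(cols, attr, numeric(1), "omega"),
            group = comps$group,
            sigma0 = sigma0, n0 = n0,
            class = c("rank_score_table", "matrix"))
}

#' Aggregate one gene's rank scores under a direction assignment
#'
#' The aggregate score of a gene is the product over its defined comparisons
#' of `-ln(t)`, where `t` is the rank score when the comparison's group
#' direction is +1 and one minus the rank score when it is -1. Undefined
#' (both-zero) comparisons are skipped. The log transform rewards genes
#' whose change is consistently extreme in the chosen directions: two scores
#' of 1e-4 and 1 - 1e-4 (extreme but opposite) aggregate to about 9.2e-4,
#' while two concordant scores of 1e-2 aggregate to about 21.2.
#'
#' @param scores Numeric vector of rank scores in (0, 1); `NA` marks
#'   undefined comparisons.
#' @param d Direction assignment: vector of +1/-1, one entry per group.
#' @param groups Integer group index per score, default all group 1.
#' @return The scalar aggregate score.
#' @export
aggregate_score <- function(scores, d = 1, groups = rep(1L, length(scores))) {
  if (length(groups) != length(scores))
    stop("groups must match scores in length", call. = FALSE)
  if (!all(d %in% c(-1, 1)))
    stop("directions must be +1 or -1", call. = FALSE)
  if (max(groups) > length(d))
    stop("direction assignment shorter than the number of groups",
         call. = FALSE)
  ok <- !is.na(scores)
  if (!any(ok))
    stop("gene has no defined comparison; cannot be scored", call. = FALSE)
  t <- ifelse(d[groups][ok] == 1, scores[ok], 1 - scores[ok])
  prod(-log(t))
}

# Vectorised aggregation for all genes and all direction assignments.
# tab: G x C score matrix (NA = undefined); group: length-C integer;
# dirs: K x N matrix of +1/-1. Returns list(score, best, n_comp) where
# score is the combined (max or min over assignments) aggregate.
aggregate_all <- function(tab, group, dirs, direction_combine = "max") {
  G <- nrow(tab)
  K <- nrow(dirs)
  n_comp <- rowSums(!is.na(tab))
  per <- matrix(NA_real_, G, K)
  for (k in seq_len(K)) {
    dcol <- dirs[k, group]
    tt <- tab
    flip <- dcol == -1
    if (any(flip)) tt[, flip] <- 1 - tt[, flip]
    L <- -log(tt)
    L[is.na(L)] <- 1
    p <- rep(1, G)
    for (j in seq_len(ncol(L))) p <- p * L[, j]
    per[, k] <- p
  }
  if (direction_combine == "max") {
    best <- max.col(per, ties.method = "first")
  } else {
    best <- max.col(-per, ties.method = "first")
  }
  score <- per[cbind(seq_len(G), best)]
  list(score = score, best = best, n_comp = n_comp)
}

#' Rank genes by consistent differential expression
#'
#' Runs the full ranking: per-comparison rank scores (with virtual scores
#' for zero-involving pairs), aggregation by the product of negative log
#' scores, and optimisation over all `2^N` per-group direction assignments.
#' The final score of a gene is by default the *maximum* aggregate over
#' assignments — equivalently, the best (minimal) rank the gene achieves in
#' any direction combination — and genes are ranked by final score from the
#' highest (rank 1, most consistently differentially expressed) down.
#' Ties in the final score are broken by input row order, so reruns are
#' reproducible.
#'
#' Genes whose every designed comparison has two zero counts cannot be
#' scored; they are excluded from the ranking and reported separately.
#'
#' @param m Count matrix (ideally after [filter_all_zero_rows()]).
#' @param design A [comparison_design()].
#' @param sigma0 Virtual rank score in (0, 0.5), default 0.1.
#' @param n0 Prior count, default 1.
#' @param direction_combine `"max"` (default) keeps the best aggregate over
#'   direction assignments; `"min"` keeps the worst, retained as an audit
#'   switch.
#' @return An object of class `protrank_ranking`: a list with
#'   * `ranking`: data.frame with columns `gene_id`, `score`, `rank`,
#'     `directions` (string of `+`/`-`, one per group, for the best
#'     assignment), `n_comparisons`;
#'   * `excluded`: gene ids with no defined comparison;
#'   * `score_table`: the underlying [rank_score_table()];
#'   * `design`, `sigma0`, `n0`, `direction_combine`.
#' @export
rank_genes <- function(m, design, sigma0 = 0.1, n0 = 1,
                       direction_combine = c("max", "min")) {
  direction_combine <- match.arg(direction_combine)
  tab <- rank_score_table(m, design, sigma0, n0)
  dirs <- enumerate_directions(n_groups(design))
  agg <- aggregate_all(tab, attr(tab, "group"), dirs, direction_combine)
  rankable <- agg$n_comp > 0
  genes <- rownames(m)[rankable]
  score <- agg$score[rankable]
  best <- agg$best[rankable]
  ord <- order(-score)    # stable: ties keep input row order
  dir_str <- apply(dirs, 1, function(d)
    paste(ifelse(d == 1, "+", "-"), collapse = ""))
  ranking <- data.frame(
    gene_id = genes[ord],
    score = score[ord],
    rank = seq_along(ord),
    directions = dir_str[best[ord]],
    n_comparisons = agg$n_comp[rankable][ord],
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(ranking = ranking,
                 excluded = rownames(m)[!rankable],
                 score_table = tab,
                 design = design,
                 sigma0 = sigma0, n0 = n0,
                 direction_combine = direction_combine),
            class = "protrank_ranking")
}

#' @export
print.protrank_ranking <- function(x, n = 10, ...) {
  cat(sprintf("protrank ranking: %d gene(s) ranked, %d excluded (all-zero comparisons)\n",
              nrow(x$ranking), length(x$excluded)))
  cat(sprintf("  groups: %d, sigma0 = %g, n0 = %g, direction combine = %s\n",
              n_groups(x$design), x$sigma0, x$n0, x$direction_combine))
  print(utils::head(x$ranking, n))
  invisible(x)
}
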