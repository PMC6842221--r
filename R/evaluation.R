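# Evaluation of gene lists and rankings against a reference set:
# precision/recall, ROC and PR curves, zero-fraction and count-bin
# representation diagnostics.

#' Precision and recall of a found gene set against a reference
#'
#' Precision is the fraction of found genes that are in the reference set;
#' recall is the fraction of the reference set that was found. With an
#' empty found set the precision is undefined and reported as `NA`.
#'
#' @param found Character vector of genes called by a method.
#' @param reference Non-empty character vector of reference genes.
#' @return Named numeric vector `c(precision = , recall = )`.
#' @export
precision_recall <- function(found, reference) {
  if (length(reference) == 0)
    stop("reference set must be non-empty", call. = FALSE)
  found <- unique(found)
  reference <- unique(reference)
  hit <- length(intersect(found, reference))
  c(precision = if (length(found) == 0) NA_real_ else hit / length(found),
    recall = hit / length(reference))
}

#' ROC and precision-recall curves for a gene ranking
#'
#' Sweeps a threshold down the ranking and records, at every depth, the
#' true/false positive rates (ROC) and precision vs recall (PR). The ROC
#' area is trapezoidal; the PR area uses step-wise integration (the sum of
#' precision at each recall increment, i.e. average precision), which
#' avoids the optimistic linear interpolation between PR points.
#'
#' @param ranking Character vector of gene ids, best first; the ranked
#'   universe.
#' @param positives Non-empty character vector of reference genes; must
#'   intersect the ranking.
#' @return A list with `roc` (data.frame `fpr`, `tpr`), `pr` (data.frame
#'   `recall`, `precision`), `auc_roc`, `auc_pr`. `auc_roc` is `NA` when
#'   the ranking contains no negatives.
#' @export
ranking_curves <- function(ranking, positives) {
  if (length(positives) == 0)
    stop("positives must be non-empty", call. = FALSE)
  if (anyDuplicated(ranking))
    stop("ranking contains duplicate gene ids", call. = FALSE)
  is_pos <- ranking %in% positives
  n_pos <- sum(is_pos)
  if (n_pos == 0)
    stop("positives are disjoint from the ranking", call. = FALSE)
  n_neg <- length(ranking) - n_pos
  tp <- cumsum(is_pos)
  fp <- cumsum(!is_pos)
  tpr <- tp / n_pos
  fpr <- if (n_neg > 0) fp / n_neg else rep(NA_real_, length(fp))
  prec <- tp / seq_along(ranking)
  rec <- tpr
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  pr <- data.frame(recall = rec, precision = prec)
  auc_roc <- if (n_neg > 0)
    sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  else NA_real_
  # average precision: precision at each positive's rank, averaged
  auc_pr <- sum(prec[is_pos]) / n_pos
  list(roc = roc, pr = pr, auc_roc = auc_roc, auc_pr = auc_pr)
}

#' Zero fraction of selected genes
#'
#' Fraction of zero counts among the selected genes' cells over the
#' selected samples — the diagnostic that reveals when a method's gene list
#' is driven by missing values rather than expression changes.
#'
#' @param m Count matrix.
#' @param genes Non-empty character vector of gene ids in `m`.
#' @param samples Sample ids to include, default all.
#' @return Proportion of zero cells.
#' @export
zero_fraction_of <- function(m, genes, samples = colnames(m)) {
  validate_counts(m)
  if (length(genes) == 0) stop("gene set must be non-empty", call. = FALSE)
  miss <- setdiff(genes, rownames(m))
  if (length(miss) > 0)
    stop("unknown gene(s): ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  mean(m[genes, samples, drop = FALSE] == 0)
}

#' Relative representation of DE genes across count bins
#'
#' Computes each gene's median positive count, log10-transforms it, bins
#' the values into `n_bins` equal-width bins over the observed range, and
#' reports per bin the fraction of all genes (`f0`), the fraction of the DE
#' set (`f_de`), and their ratio. A ratio above 1 means genes of that
#' abundance are over-represented among the DE calls; an unbiased selection
#' has all defined ratios near 1. Bins containing no genes are reported
#' with `NA` ratios rather than 0.
#'
#' @param m Count matrix; every gene needs at least one positive count.
#' @param de_genes Non-empty character vector of DE gene ids.
#' @param n_bins Number of bins, default 10.
#' @return data.frame with columns `bin`, `lower`, `upper` (log10 median
#'   count bounds), `f0`, `f_de`, `ratio`.
#' @export
relative_representation <- function(m, de_genes, n_bins = 10) {
  validate_counts(m)
  if (length(de_genes) == 0) stop("de_genes must be non-empty", call. = FALSE)
  miss <- setdiff(de_genes, rownames(m))
  if (length(miss) > 0)
    stop("unknown gene(s): ", paste(utils::head(miss, 3), collapse = ", "),
         call. = FALSE)
  med <- apply(m, 1, function(r) {
    p <- r[r > 0]
    if (length(p) == 0)
      stop("gene with no positive counts; filter all-zero rows first",
           call. = FALSE)
    stats::median(p)
  })
  lg <- log10(med)
  rng <- range(lg)
  if (rng[1] == rng[2]) {
    breaks <- c(rng[1] - 0.5, rng[1] + 0.5)
    n_bins <- 1L
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  bin <- cut(lg, breaks, include.lowest = TRUE, labels = FALSE)
  f0 <- tabulate(bin, nbins = n_bins) / length(lg)
  f_de <- tabulate(bin[names(lg) %in% de_genes], nbins = n_bins) /
    length(de_genes)
  ratio <- ifelse(f0 > 0, f_de / f0, NA_real_)
  data.frame(bin = seq_len(n_bins),
             lower = utils::head(breaks, -1),
             upper = utils::tail(breaks, -1),
             f0 = f0, f_de = f_de, ratio = ratio)
}
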