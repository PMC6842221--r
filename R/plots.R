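# Base-graphics diagnostics.

#' Rank plot of real vs bootstrap aggregate scores
#'
#' Plots the sorted final aggregate scores of the real data against their
#' rank, overlaid with the mean (and +/- one sd band) of the bootstrap
#' realizations. When true DE genes exist, the real curve dominates the
#' bootstrap curve at the top ranks; the crossing region is where FDR
#' estimates approach 1.
#'
#' @param fdr A [estimate_fdr()] result.
#' @param top Number of top ranks to show, default all.
#' @param log_y Log-scale the score axis, default TRUE.
#' @return Invisibly, a data.frame `rank`, `real`, `boot_mean`, `boot_sd`.
#' @export
plot_rank_scores <- function(fdr, top = NULL, log_y = TRUE) {
  stopifnot(inherits(fdr, "protrank_fdr"))
  real <- fdr$table$score
  bm <- rowMeans(fdr$boot_scores)
  bs <- apply(fdr$boot_scores, 1, stats::sd)
  k <- if (is.null(top)) length(real) else min(top, length(real))
  idx <- seq_len(k)
  ylim <- range(c(real[idx], bm[idx] + bs[idx], pmax(bm[idx] - bs[idx], 0)))
  if (log_y) ylim[1] <- max(ylim[1], min(real[idx][real[idx] > 0], na.rm = TRUE) / 10)
  graphics::plot(idx, real[idx], type = "l", lwd = 2, col = "black",
                 log = if (log_y) "y" else "",
                 xlab = "rank", ylab = "final aggregate score",
                 ylim = ylim, main = "real vs bootstrap rank scores")
  graphics::polygon(c(idx, rev(idx)),
                    c(pmax(bm[idx] - bs[idx], ylim[1]), rev(bm[idx] + bs[idx])),
                    border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
  graphics::lines(idx, bm[idx], col = "steelblue", lwd = 2)
  graphics::legend("topright", c("real", "bootstrap mean"),
                   col = c("black", "steelblue"), lwd = 2, bty = "n")
  invisible(data.frame(rank = idx, real = real[idx],
                       boot_mean = bm[idx], boot_sd = bs[idx]))
}

#' Plot ROC and PR curves
#'
#' @param curves A [ranking_curves()] result.
#' @param which `"roc"`, `"pr"`, or `"both"` (default; side by side).
#' @return `curves`, invisibly.
#' @export
plot_curves <- function(curves, which = c("both", "roc", "pr")) {
  which <- match.arg(which)
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (which %in% c("both", "roc")) {
    graphics::plot(curves$roc$fpr, curves$roc$tpr, type = "l", lwd = 2,
                   xlab = "false positive rate", ylab = "true positive rate",
                   main = sprintf("ROC (AUC = %.3f)", curves$auc_roc))
    graphics::abline(0, 1, lty = 2, col = "grey")
  }
  if (which %in% c("both", "pr")) {
    graphics::plot(curves$pr$recall, curves$pr$precision, type = "l", lwd = 2,
                   xlab = "recall", ylab = "precision", ylim = c(0, 1),
                   main = sprintf("PR (AUC = %.3f)", curves$auc_pr))
  }
  invisible(curves)
}
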