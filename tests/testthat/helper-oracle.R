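# Independent brute-force reimplementation of the ranking pipeline, written
# as plain loops with no code shared with the package. Used as the oracle
# for small-instance equivalence tests.

oracle_rank <- function(m, design, sigma0 = 0.1, n0 = 1, combine = "max") {
  comps <- list()
  for (n in seq_along(design$groups)) {
    g <- design$groups[[n]]
    for (j in seq_len(nrow(g)))
      comps[[length(comps) + 1L]] <- list(group = n, b = g[j, 1], a = g[j, 2])
  }
  G <- nrow(m)
  C <- length(comps)
  S <- matrix(NA_real_, G, C)
  for (k in seq_len(C)) {
    b <- m[, comps[[k]]$b]
    a <- m[, comps[[k]]$a]
    pos <- which(b > 0 & a > 0)
    x <- numeric(0)
    if (length(pos) > 0) x <- log2((a[pos] + n0) / (b[pos] + n0))
    for (g in seq_len(G)) {
      if (b[g] == 0 && a[g] == 0) next
      if (b[g] == 0) { S[g, k] <- sigma0; next }
      if (a[g] == 0) { S[g, k] <- 1 - sigma0; next }
      xg <- log2((a[g] + n0) / (b[g] + n0))
      # descending rank with average ties
      r <- sum(x > xg) + (sum(x == xg) + 1) / 2
      S[g, k] <- (r - 0.5) / length(pos)
    }
  }
  N <- length(design$groups)
  # enumerate directions: bit pattern, group 1 most significant, 0 -> +1
  dir_rows <- vector("list", 2^N)
  for (k in 0:(2^N - 1)) {
    d <- integer(N)
    for (n in seq_len(N))
      d[n] <- if (bitwAnd(k, bitwShiftL(1L, N - n)) == 0) 1L else -1L
    dir_rows[[k + 1]] <- d
  }
  score <- rep(NA_real_, G)
  best <- rep(NA_integer_, G)
  for (g in seq_len(G)) {
    defined <- which(!is.na(S[g, ]))
    if (length(defined) == 0) next
    for (k in seq_along(dir_rows)) {
      d <- dir_rows[[k]]
      p <- 1
      for (j in defined) {
        dn <- d[comps[[j]]$group]
        t <- if (dn == 1) S[g, j] else 1 - S[g, j]
        p <- p * (-log(t))
      }
      better <- if (combine == "max") {
        is.na(score[g]) || p > score[g]
      } else {
        is.na(score[g]) || p < score[g]
      }
      if (better) { score[g] <- p; best[g] <- k }
    }
  }
  rankable <- which(!is.na(score))
  ord <- rankable[order(-score[rankable])]
  dir_str <- vapply(dir_rows, function(d)
    paste(ifelse(d == 1, "+", "-"), collapse = ""), character(1))
  list(
    ranking = data.frame(gene_id = rownames(m)[ord],
                         score = score[ord],
                         rank = seq_along(ord),
                         directions = dir_str[best[ord]],
                         stringsAsFactors = FALSE, row.names = NULL),
    excluded = rownames(m)[is.na(score)],
    score_table = S)
}

# random count matrix with zero inflation, for property tests
random_counts <- function(n_genes, n_samples, zero_prob = 0.25,
                          max_count = 30) {
  m <- matrix(sample(0:max_count, n_genes * n_samples, replace = TRUE,
                     prob = c(rep(zero_prob / 1, 1),
                              rep((1 - zero_prob) / max_count, max_count))),
              n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  m
}
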