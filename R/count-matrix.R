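# Count-table data model: a validated numeric matrix with gene ids as
# rownames and sample ids as colnames. Zeros encode missing values.

#' Validate a count matrix
#'
#' Checks that `m` is a numeric matrix of nonnegative, finite counts with
#' unique, non-empty gene and sample identifiers. Zeros are the missing-value
#' encoding throughout the package; `NA` entries are rejected.
#'
#' @param m A numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @return `m`, invisibly, if valid. Otherwise an error is signalled.
#' @export
validate_counts <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("counts must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("counts must carry gene ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene id(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid count (negative, missing or non-finite) at gene '%s', sample '%s'",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  invisible(m)
}

#' Read a delimited count table
#'
#' Reads a genes x samples table of nonnegative counts from delimited text.
#' The file must have a header row of sample names; one column holds the gene
#' identifiers. Cells that do not parse as nonnegative numbers, missing cells,
#' and duplicated identifiers are rejected rather than silently coerced.
#'
#' @param path Path to the table.
#' @param delimiter Field separator, default tab.
#' @param id_column Column (name or 1-based index) holding gene identifiers,
#'   default the first column.
#' @return A validated numeric count matrix (genes x samples).
#' @seealso [write_counts()], [validate_counts()]
#' @export
read_counts <- function(path, delimiter = "\t", id_column = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "",
                          quote = "\"")
  if (ncol(df) < 2)
    stop("count table needs an id column and at least one sample column",
         call. = FALSE)
  if (is.character(id_column)) {
    idx <- match(id_column, colnames(df))
    if (is.na(idx)) stop("id column '", id_column, "' not found", call. = FALSE)
  } else {
    idx <- as.integer(id_column)
    if (idx < 1 || idx > ncol(df)) stop("id column index out of range",
                                        call. = FALSE)
  }
  ids <- df[[idx]]
  dat <- df[, -idx, drop = FALSE]
  samples <- colnames(dat)
  m <- matrix(NA_real_, nrow = nrow(dat), ncol = ncol(dat),
              dimnames = list(ids, samples))
  for (j in seq_along(dat)) {
    v <- suppressWarnings(as.numeric(dat[[j]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0)
      stop(sprintf("cell does not parse as a number at gene '%s', sample '%s'",
                   ids[bad[1]], samples[j]), call. = FALSE)
    m[, j] <- v
  }
  validate_counts(m)
  m
}

#' Write a count table as delimited text
#'
#' Emits the same dialect [read_counts()] consumes, so integer tables
#' round-trip bit-identically.
#'
#' @param m Count matrix.
#' @param path Output path.
#' @param delimiter Field separator, default tab.
#' @param id_name Header name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, delimiter = "\t", id_name = "id") {
  validate_counts(m)
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_name, colnames(m))
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Drop genes with no positive count
#'
#' Genes whose counts are zero in every sample carry no information for a
#' rank-based analysis and are removed before ranking.
#'
#' @param m Count matrix.
#' @return A list with `counts` (the filtered matrix) and `removed`
#'   (character vector of dropped gene ids).
#' @export
filter_all_zero_rows <- function(m) {
  validate_counts(m)
  keep <- rowSums(m > 0) > 0
  list(counts = m[keep, , drop = FALSE],
       removed = rownames(m)[!keep])
}

#' Missing-value diagnostics for a count table
#'
#' Summarises the zero structure of a count table relative to a comparison
#' design: the overall zero fraction, the median of the positive counts, the
#' fraction of designed gene x comparison pairs that contain an *irregular
#' zero* (exactly one count zero while the other exceeds the median positive
#' count), and the conditional probability that the partner of an
#' above-median count is zero. Irregular zeros are the pathological case for
#' prior-count shrinkage of log fold changes: no pseudocount of reasonable
#' size tames a change from an above-median intensity to zero.
#'
#' @param m Count matrix.
#' @param design A [comparison_design()] whose sample ids occur in `m`.
#' @return An object of class `protrank_data_stats`: a list with elements
#'   `n_genes`, `n_samples`, `n_comparisons`, `zero_fraction`,
#'   `median_positive`, `irregular_zero_fraction`, `p_zero_given_large`.
#' @export
data_stats <- function(m, design) {
  validate_counts(m)
  comps <- design_comparisons(design)
  miss <- setdiff(unique(c(comps$before, comps$after)), colnames(m))
  if (length(miss) > 0)
    stop("design references unknown sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  pos <- m[m > 0]
  med <- if (length(pos) > 0) stats::median(pos) else NA_real_
  n_irr <- 0L
  n_large <- 0L
  n_large_zero <- 0L
  for (k in seq_len(nrow(comps))) {
    b <- m[, comps$before[k]]
    a <- m[, comps$after[k]]
    n_irr <- n_irr + sum((b == 0 & a > med) | (a == 0 & b > med))
    # each pair yields two ordered (count, partner) occurrences
    n_large <- n_large + sum(b > med) + sum(a > med)
    n_large_zero <- n_large_zero + sum(b > med & a == 0) + sum(a > med & b == 0)
  }
  n_pairs <- nrow(m) * nrow(comps)
  structure(list(
    n_genes = nrow(m),
    n_samples = ncol(m),
    n_comparisons = nrow(comps),
    zero_fraction = mean(m == 0),
    median_positive = med,
    irregular_zero_fraction = if (n_pairs > 0) n_irr / n_pairs else NA_real_,
    p_zero_given_large = if (n_large > 0) n_large_zero / n_large else NA_real_
  ), class = "protrank_data_stats")
}

#' @export
print.protrank_data_stats <- function(x, ...) {
  cat(sprintf("count table: %d genes x %d samples, %d designed comparison(s)\n",
              x$n_genes, x$n_samples, x$n_comparisons))
  cat(sprintf("  zero fraction:            %.3f\n", x$zero_fraction))
  cat(sprintf("  median positive count:    %g\n", x$median_positive))
  cat(sprintf("  irregular-zero fraction:  %.4f\n", x$irregular_zero_fraction))
  cat(sprintf("  P(partner zero | count > median): %.4f\n",
              x$p_zero_given_large))
  invisible(x)
}
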