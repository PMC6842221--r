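# Comparison designs: ordered (before, after) sample pairs organised into
# groups that are expected to change in the same direction.

#' Construct a comparison design
#'
#' A design is a list of comparison groups; each group is a set of ordered
#' (before, after) sample pairs expected to move in the same direction under
#' the studied condition. Groups may move in independent directions: the
#' ranking step optimises over all per-group direction assignments.
#'
#' @param groups A list with one element per group. Each element is either a
#'   two-column matrix / data.frame (columns before, after) or a list of
#'   length-2 character vectors `c(before, after)`.
#' @param group_names Optional character names for the groups.
#' @return An object of class `comparison_design`.
#' @examples
#' d <- comparison_design(list(rbind(c("C_1", "IR1h_1"), c("C_2", "IR1h_2"))))
#' n_groups(d)
#' @export
comparison_design <- function(groups, group_names = NULL) {
  if (!is.list(groups) || length(groups) < 1)
    stop("a design needs at least one group of comparisons", call. = FALSE)
  norm <- lapply(groups, function(g) {
    if (is.data.frame(g)) g <- as.matrix(g)
    if (is.list(g) && !is.data.frame(g)) g <- do.call(rbind, g)
    if (is.null(dim(g)) && length(g) == 2) g <- matrix(g, nrow = 1)
    if (!is.matrix(g) || ncol(g) != 2 || nrow(g) < 1)
      stop("each group must be a non-empty set of (before, after) pairs",
           call. = FALSE)
    g <- matrix(as.character(g), ncol = 2)
    if (any(g[, 1] == g[, 2]))
      stop("a comparison cannot pair a sample with itself: ",
           g[g[, 1] == g[, 2], 1][1], call. = FALSE)
    colnames(g) <- c("before", "after")
    g
  })
  if (is.null(group_names)) group_names <- paste0("group", seq_along(norm))
  if (length(group_names) != length(norm))
    stop("group_names length must match the number of groups", call. = FALSE)
  names(norm) <- group_names
  structure(list(groups = norm), class = "comparison_design")
}

#' Single-group design from before/after sample vectors
#'
#' Shorthand for the common case where every comparison is expected to move
#' in the same direction, e.g. treated vs control duplicates.
#'
#' @param before,after Equal-length character vectors of sample ids;
#'   `before[i]` is compared against `after[i]`.
#' @return A `comparison_design` with one group.
#' @export
single_group_design <- function(before, after) {
  if (length(before) != length(after) || length(before) < 1)
    stop("before and after must be non-empty vectors of equal length",
         call. = FALSE)
  comparison_design(list(cbind(before, after)))
}

#' Number of comparison groups
#' @param design A `comparison_design`.
#' @return Integer number of groups N.
#' @export
n_groups <- function(design) {
  stopifnot(inherits(design, "comparison_design"))
  length(design$groups)
}

#' Flatten a design into a comparison table
#'
#' @param design A `comparison_design`.
#' @return A data.frame with columns `group` (integer index), `group_name`,
#'   `before`, `after`; one row per comparison, in design order.
#' @export
design_comparisons <- function(design) {
  stopifnot(inherits(design, "comparison_design"))
  out <- do.call(rbind, lapply(seq_along(design$groups), function(n) {
    g <- design$groups[[n]]
    data.frame(group = n, group_name = names(design$groups)[n],
               before = g[, 1], after = g[, 2],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Parse a design file
#'
#' Plain-text design format: one comparison per line as
#' `before<TAB>after` (any whitespace accepted); a blank line starts a new
#' group; `#` starts a comment. A file with no blank lines is a single-group
#' design, the common case for replicate before/after comparisons.
#'
#' @param path Path to a design file, or a character vector of lines via
#'   `text`.
#' @param text Optional character vector of lines (overrides `path`).
#' @return A `comparison_design`.
#' @export
parse_design <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else {
    if (is.null(path) || !file.exists(path))
      stop("design file not found: ", path, call. = FALSE)
    readLines(path)
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  groups <- list()
  current <- list()
  flush <- function() {
    if (length(current) > 0) groups[[length(groups) + 1L]] <<- current
    current <<- list()
  }
  for (ln in lines) {
    if (ln == "") { flush(); next }
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(parts) != 2)
      stop("design line must contain exactly two sample ids: '", ln, "'",
           call. = FALSE)
    current[[length(current) + 1L]] <- parts
  }
  flush()
  if (length(groups) == 0)
    stop("design file contains no comparisons", call. = FALSE)
  comparison_design(groups)
}

#' Parse a `before:after,before:after` pair list
#'
#' CLI shorthand for a single-group design.
#'
#' @param pairs A string like `"C_1:IR_1,C_2:IR_2"`.
#' @return A `comparison_design` with one group.
#' @export
parse_pairs <- function(pairs) {
  items <- strsplit(pairs, ",", fixed = TRUE)[[1]]
  items <- trimws(items)
  items <- items[items != ""]
  if (length(items) == 0) stop("no pairs given", call. = FALSE)
  mat <- t(vapply(items, function(p) {
    parts <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("pair must be 'before:after': '", p, "'", call. = FALSE)
    parts
  }, character(2)))
  comparison_design(list(mat))
}

#' Write a design file
#'
#' @param design A `comparison_design`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "comparison_design"))
  blocks <- vapply(design$groups, function(g)
    paste(paste(g[, 1], g[, 2], sep = "\t"), collapse = "\n"), character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Enumerate all per-group direction assignments
#'
#' A direction assignment labels every comparison group with +1 (search for
#' upregulation in that group) or -1 (downregulation). All `2^N` assignments
#' are enumerated in a fixed lexicographic order with +1 before -1, so the
#' first row is all +1 and the last all -1.
#'
#' @param n Number of groups (or a `comparison_design`).
#' @param max_groups Safety cap on N; enumeration is exhaustive in `2^N`.
#' @return An integer matrix of dimension `2^N x N` with entries in
#'   `c(1L, -1L)`.
#' @export
enumerate_directions <- function(n, max_groups = 12) {
  if (inherits(n, "comparison_design")) n <- n_groups(n)
  n <- as.integer(n)
  if (n < 1) stop("need at least one group", call. = FALSE)
  if (n > max_groups)
    stop("refusing to enumerate 2^", n,
         " direction assignments (cap ", max_groups, ")", call. = FALSE)
  cols <- lapply(seq_len(n), function(j)
    rep(rep(c(1L, -1L), each = 2^(n - j)), times = 2^(j - 1)))
  do.call(cbind, cols)
}

#' @export
print.comparison_design <- function(x, ...) {
  comps <- design_comparisons(x)
  cat(sprintf("comparison design: %d group(s), %d comparison(s)\n",
              n_groups(x), nrow(comps)))
  for (n in seq_along(x$groups)) {
    g <- x$groups[[n]]
    cat(sprintf("  %s: %s\n", names(x$groups)[n],
                paste(paste0(g[, 1], "->", g[, 2]), collapse = ", ")))
  }
  invisible(x)
}
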