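IUPAC_MISSING <- c("N", "-", "?", "M", "R", "W", "S", "Y", "K", "V", "H", "D", "B")

#' Construct an alignment object
#'
#' An alignment is a taxa x columns character matrix (upper-case IUPAC DNA,
#' `-` for gaps) with unique row names and, optionally, an attached
#' [partition_set()].
#'
#' @param x Named list of equal-length sequence strings (e.g. from
#'   [read_fasta()]) or a character matrix with row names.
#' @param partition Optional [partition_set()] over the columns.
#' @return A matrix of class `plast_alignment`.
#' @export
as_alignment <- function(x, partition = NULL) {
  if (is.matrix(x)) {
    mat <- x
  } else {
    lens <- nchar(unlist(x))
    if (length(unique(lens)) != 1L)
      stop("sequences have unequal lengths (", paste(range(lens), collapse = "-"),
           "); align them first")
    mat <- do.call(rbind, strsplit(toupper(unlist(x)), ""))
    rownames(mat) <- names(x)
  }
  if (is.null(rownames(mat)) || any(duplicated(rownames(mat))))
    stop("alignment requires unique taxon names")
  if (nrow(mat) < 2L) stop("alignment needs at least 2 taxa")
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "partition_set"))
    if (partition$n_columns != ncol(mat))
      stop("partition is over ", partition$n_columns, " columns but alignment has ", ncol(mat))
  }
  structure(mat, class = c("plast_alignment", class(mat)), partition = partition)
}

#' @export
print.plast_alignment <- function(x, ...) {
  cat("<plast_alignment> ", nrow(x), " taxa x ", ncol(x), " columns\n", sep = "")
  if (!is.null(attr(x, "partition")))
    cat("  partitions: ", paste(names(attr(x, "partition")$partitions), collapse = ", "), "\n", sep = "")
  invisible(x)
}

alignment_taxa <- function(alignment) rownames(alignment)

missing_mask <- function(mat) {
  matrix(mat %in% IUPAC_MISSING, nrow = nrow(mat))
}

#' Classify alignment columns (constant / variable / parsimony-informative)
#'
#' Per-column classification with gaps, `N` and ambiguity codes treated as
#' missing. Under `gap_mode = "missing"` a column is constant when at most
#' one distinct non-missing state is present, variable when two or more are;
#' a variable column is parsimony-informative when at least two states each
#' occur in at least two taxa, otherwise it is a singleton site. Under
#' `gap_mode = "delete_columns"` every column containing a gap in any
#' retained taxon is removed first (counted in `n_excluded`), reproducing a
#' manual deletion of indels.
#'
#' @param alignment A [as_alignment()] matrix.
#' @param gap_mode `"missing"` or `"delete_columns"`.
#' @param exclude_taxa Taxa dropped before counting (e.g. the out-group).
#' @return A list of class `site_classification`: `n_constant`, `n_variable`,
#'   `n_parsimony_informative`, `n_singleton`, `n_excluded`, `column_count`.
#' @export
classify_sites <- function(alignment, gap_mode = c("missing", "delete_columns"),
                           exclude_taxa = character(0)) {
  gap_mode <- match.arg(gap_mode)
  mat <- drop_taxa(alignment, exclude_taxa)
  total <- ncol(mat)
  n_excluded <- 0L
  if (gap_mode == "delete_columns") {
    keep <- colSums(matrix(mat == "-", nrow = nrow(mat))) == 0L
    n_excluded <- sum(!keep)
    if (all(!keep)) stop("all columns contain gaps; nothing left to classify")
    mat <- mat[, keep, drop = FALSE]
  }
  counts <- column_state_counts(mat)
  n_states <- colSums(counts > 0L)
  n_pi_states <- colSums(counts >= 2L)
  constant <- n_states <= 1L
  pi <- n_states >= 2L & n_pi_states >= 2L
  structure(list(
    n_constant = sum(constant),
    n_variable = sum(!constant),
    n_parsimony_informative = sum(pi),
    n_singleton = sum(!constant & !pi),
    n_excluded = n_excluded,
    column_count = total
  ), class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("Sites: ", x$column_count, " columns | constant ", x$n_constant,
      " | variable ", x$n_variable, " (PI ", x$n_parsimony_informative,
      ", singleton ", x$n_singleton, ") | excluded ", x$n_excluded, "\n", sep = "")
  invisible(x)
}

# 4 x ncol matrix of A/C/G/T counts per column, missing ignored
column_state_counts <- function(mat) {
  rbind(A = colSums(mat == "A"), C = colSums(mat == "C"),
        G = colSums(mat == "G"), T = colSums(mat == "T"))
}

drop_taxa <- function(alignment, exclude_taxa) {
  if (length(exclude_taxa)) {
    missing <- setdiff(exclude_taxa, rownames(alignment))
    if (length(missing)) stop("taxa to exclude not in alignment: ",
                              paste(missing, collapse = ", "))
    alignment <- alignment[setdiff(rownames(alignment), exclude_taxa), , drop = FALSE]
    if (nrow(alignment) < 2L) stop("exclusion leaves fewer than 2 taxa")
  }
  alignment
}

#' Count pairwise nucleotide differences between two taxa
#'
#' Columns where either taxon is missing (gap, `N`, ambiguity) are skipped;
#' with `gap_mode = "delete_columns"` every column containing a gap in any
#' taxon of the alignment is removed before counting.
#'
#' @inheritParams classify_sites
#' @param taxon_a,taxon_b Taxon labels.
#' @return Integer count of differing, jointly called columns.
#' @export
pairwise_differences <- function(alignment, taxon_a, taxon_b,
                                 gap_mode = c("missing", "delete_columns")) {
  gap_mode <- match.arg(gap_mode)
  for (tx in c(taxon_a, taxon_b))
    if (!tx %in% rownames(alignment)) stop("unknown taxon: ", tx)
  if (gap_mode == "delete_columns") alignment <- strip_gap_columns(alignment)
  a <- alignment[taxon_a, ]
  b <- alignment[taxon_b, ]
  ok <- !(a %in% IUPAC_MISSING) & !(b %in% IUPAC_MISSING)
  sum(a[ok] != b[ok])
}

#' Full matrix of pairwise differences
#' @inheritParams pairwise_differences
#' @return Symmetric integer matrix with taxa as dimnames.
#' @export
pairwise_difference_matrix <- function(alignment, gap_mode = "missing") {
  taxa <- rownames(alignment)
  n <- length(taxa)
  m <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- pairwise_differences(alignment, taxa[i], taxa[j], gap_mode)
  }
  m
}

#' Remove every column containing a gap
#'
#' @param alignment A [as_alignment()] matrix.
#' @return The alignment restricted to gap-free columns (taxa order kept).
#' @export
strip_gap_columns <- function(alignment) {
  keep <- colSums(matrix(alignment == "-", nrow = nrow(alignment))) == 0L
  if (!any(keep)) stop("stripping gap columns leaves an empty alignment")
  part <- attr(alignment, "partition")
  out <- alignment[, keep, drop = FALSE]
  class(out) <- class(alignment)
  attr(out, "partition") <- NULL  # column coordinates no longer apply
  out
}

#' Restrict an alignment to a set of columns
#' @param alignment A [as_alignment()] matrix.
#' @param columns 1-based column indices to keep.
#' @return The sub-alignment (partition dropped).
#' @export
subset_columns <- function(alignment, columns) {
  out <- alignment[, columns, drop = FALSE]
  class(out) <- class(alignment)
  attr(out, "partition") <- NULL
  out
}
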