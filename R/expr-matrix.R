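#' Expression matrix container
#'
#' A light wrapper around an integer gene-by-sample count matrix that carries
#' per-sample size factors once the matrix has been normalized. Counts are
#' genes in rows, samples in columns; identifiers must be unique.
#'
#' @param counts numeric matrix of non-negative counts with rownames (genes)
#'   and colnames (samples).
#' @param size_factors optional positive numeric vector, one per sample.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(counts, size_factors = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(size_factors)) {
    if (length(size_factors) != ncol(counts))
      stop("size_factors must have one entry per sample")
    if (any(size_factors <= 0)) stop("size_factors must be positive")
    if (is.null(names(size_factors))) names(size_factors) <- colnames(counts)
  }
  structure(list(counts = counts, size_factors = size_factors),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$size_factors)) "raw" else "normalized"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

#' Raw counts of an expression matrix
#' @param x an `expr_matrix`.
#' @return The integer count matrix.
#' @export
counts <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  x$counts
}

#' Normalized counts (count / size factor)
#'
#' Requires size factors, as computed by [median_of_ratios_normalize()].
#' @param x an `expr_matrix` with size factors.
#' @return Matrix of normalized counts.
#' @export
normalized_counts <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(x$size_factors))
    stop("expression matrix has no size factors; run median_of_ratios_normalize() first")
  sweep(x$counts, 2, x$size_factors, "/")
}

#' Read / write a gene-by-sample count matrix as TSV
#'
#' First column holds gene identifiers, the header row holds sample
#' identifiers.
#' @param path file path.
#' @return `read_counts_tsv` returns an `expr_matrix`.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expr_matrix(m)
}

#' @rdname read_counts_tsv
#' @param x an `expr_matrix`.
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
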