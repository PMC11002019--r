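# Directed gene sets and rank-based single-sample signature scoring.
#
# The score of sample i against a directed set is the mean of the directed
# ranks of the observed set genes: all G genes of the sample are ranked once
# (ties averaged); expected-up genes contribute their increasing-abundance
# rank, expected-down genes the decreasing rank G + 1 - r. Set genes absent
# from the data are excluded from both the sum and the divisor.

#' Construct a directed (signed) gene set
#'
#' @param name set name.
#' @param up genes expected up-regulated (weight +1).
#' @param down genes expected down-regulated (weight -1).
#' @param provenance free-text note on where the set came from.
#' @return A `directed_gene_set` with a named weight vector in {+1, -1}.
#' @export
directed_gene_set <- function(name, up = character(), down = character(),
                              provenance = "") {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)))
    stop("a gene cannot carry both signs: ",
         paste(intersect(up, down), collapse = ", "))
  if (length(up) + length(down) == 0)
    stop("a directed gene set needs at least one gene")
  w <- c(rep(1, length(up)), rep(-1, length(down)))
  names(w) <- c(up, down)
  structure(list(name = name, weights = w, provenance = provenance),
            class = "directed_gene_set")
}

#' @export
print.directed_gene_set <- function(x, ...) {
  cat(sprintf("directed_gene_set '%s': %d up, %d down\n", x$name,
              sum(x$weights > 0), sum(x$weights < 0)))
  invisible(x)
}

#' Build a directed signature from a differential-expression table
#'
#' Genes with `padj < alpha` are signed by their fold change: up in the
#' resistant class (log2fc > 0, with `group_a` = resistant) get +1, up in the
#' responder class get -1. DE must have been run resistant-vs-CR with PR
#' samples excluded upstream.
#'
#' @param de data.frame from [differential_expression()].
#' @param alpha adjusted-p threshold.
#' @param name signature name.
#' @return A [directed_gene_set()].
#' @export
build_directed_signature <- function(de, alpha = 0.05, name = "YIM") {
  sig <- de[de$padj < alpha & de$log2fc != 0, , drop = FALSE]
  if (!nrow(sig))
    stop("empty signature: no gene passes adjusted p < ", alpha)
  directed_gene_set(name,
                    up = sig$gene[sig$log2fc > 0],
                    down = sig$gene[sig$log2fc < 0],
                    provenance = sprintf("DE-derived at padj < %g", alpha))
}

#' Directed mean-rank score for one sample
#'
#' @param sample_expression named numeric vector: expression of every gene in
#'   the sample (any monotone scale; only ranks matter).
#' @param gene_set a [directed_gene_set()].
#' @param normalize if TRUE, rescale the mean rank to `[0, 1]` via
#'   `(score - 1) / (G - 1)`.
#' @param method "pooled" (single mean over all directed ranks, the default)
#'   or "two_block" (sum of the separate up-block and down-block mean ranks).
#' @return List: `score`, `n_used`, `ranks_used` (directed rank per used gene).
#' @export
directed_rank_score <- function(sample_expression, gene_set,
                                normalize = FALSE,
                                method = c("pooled", "two_block")) {
  method <- match.arg(method)
  stopifnot(inherits(gene_set, "directed_gene_set"))
  G <- length(sample_expression)
  present <- intersect(names(gene_set$weights), names(sample_expression))
  if (!length(present))
    stop("undefined score: no gene of set '", gene_set$name,
         "' is present in the sample")
  r <- rank(sample_expression, ties.method = "average")
  w <- gene_set$weights[present]
  dir_rank <- ifelse(w > 0, r[present], G + 1 - r[present])
  names(dir_rank) <- present
  score <- if (method == "pooled") mean(dir_rank) else {
    blocks <- c(if (any(w > 0)) mean(dir_rank[w > 0]),
                if (any(w < 0)) mean(dir_rank[w < 0]))
    sum(blocks)
  }
  if (normalize) score <- (score - 1) / (G - 1)
  list(score = score, n_used = length(present), ranks_used = dir_rank)
}

#' Score every sample of a cohort against a directed gene set
#'
#' Within-sample ranks are unaffected by per-sample scaling, so raw counts and
#' size-factor-normalized counts give identical scores.
#'
#' @param x an [expr_matrix()] or a genes-by-samples matrix.
#' @inheritParams directed_rank_score
#' @return data.frame: sample, score, n_used. Samples with no set gene
#'   present get NA with a warning.
#' @export
score_cohort <- function(x, gene_set, normalize = FALSE,
                         method = c("pooled", "two_block")) {
  method <- match.arg(method)
  m <- if (inherits(x, "expr_matrix")) x$counts else as.matrix(x)
  if (!ncol(m)) stop("empty expression matrix")
  res <- lapply(colnames(m), function(s) {
    v <- m[, s]; names(v) <- rownames(m)
    tryCatch(directed_rank_score(v, gene_set, normalize, method),
             error = function(e) NULL)
  })
  bad <- vapply(res, is.null, logical(1))
  if (any(bad))
    warning("undefined score for sample(s): ",
            paste(colnames(m)[bad], collapse = ", "))
  data.frame(
    sample = colnames(m),
    score = vapply(res, function(r) if (is.null(r)) NA_real_ else r$score,
                   numeric(1)),
    n_used = vapply(res, function(r) if (is.null(r)) 0L else r$n_used,
                    integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Merge signed component sets into one composite directed set
#'
#' Used to assemble IMMU-style composites: effector components are pooled
#' with weight +1, suppressive components with weight -1. A gene named in
#' both directions is dropped with a warning (ambiguous direction).
#'
#' @param positive list of character vectors (or `directed_gene_set`s whose
#'   genes are all taken as +1).
#' @param negative like `positive`, weighted -1.
#' @param name composite name.
#' @return A [directed_gene_set()].
#' @export
merge_directed_sets <- function(positive, negative, name = "IMMU") {
  genes_of <- function(s) if (inherits(s, "directed_gene_set"))
    names(s$weights) else as.character(s)
  up <- unique(unlist(lapply(positive, genes_of)))
  down <- unique(unlist(lapply(negative, genes_of)))
  both <- intersect(up, down)
  if (length(both)) {
    warning("dropping genes with ambiguous direction: ",
            paste(both, collapse = ", "))
    up <- setdiff(up, both); down <- setdiff(down, both)
  }
  directed_gene_set(name, up, down, provenance = "merged composite")
}

#' Immunophenogram category profiles
#'
#' Per gene, z = (value - cross-sample mean) / cross-sample SD (n-1
#' denominator); zero-variance genes get z = 0. A category's score is the
#' arithmetic mean of its marker genes' z-scores over the genes present in
#' the matrix; categories with no gene present get NA (flagged in the
#' `missing_categories` attribute).
#'
#' @param x an [expr_matrix()] (normalized values are used when size factors
#'   are present) or a plain matrix; needs >= 2 samples.
#' @param categories named list: category -> marker gene vector. Defaults to
#'   the packaged editable marker lists.
#' @return data.frame, one row per sample, one column per category.
#' @export
immunophenogram_scores <- function(x, categories = immunophenogram_categories()) {
  m <- if (inherits(x, "expr_matrix")) {
    if (is.null(x$size_factors)) x$counts else normalized_counts(x)
  } else as.matrix(x)
  if (ncol(m) < 2) stop("immunophenogram z-scores need at least 2 samples")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  out <- data.frame(sample = colnames(m), stringsAsFactors = FALSE)
  missing <- character()
  for (cat in names(categories)) {
    genes <- intersect(categories[[cat]], rownames(m))
    if (!length(genes)) {
      out[[cat]] <- NA_real_
      missing <- c(missing, cat)
    } else {
      out[[cat]] <- colMeans(z[genes, , drop = FALSE])
    }
  }
  attr(out, "missing_categories") <- missing
  out
}

#' Stratify samples on an immunophenogram category score
#'
#' A reconstruction of the qualitative spatiotype grouping: samples at or
#' above the threshold on the chosen category's mean z-score are labelled
#' `high_label`, the rest `low_label`. The threshold rule is not printed in
#' the source methods and is exposed as a parameter.
#'
#' @param profile output of [immunophenogram_scores()].
#' @param category column to threshold.
#' @param threshold cut point on the mean z-score (default 0).
#' @param high_label,low_label group names.
#' @return Named character vector of group labels.
#' @export
immunophenogram_stratify <- function(profile, category = "suppressor_cells",
                                     threshold = 0,
                                     high_label = "SIL_high",
                                     low_label = "SIL_low") {
  stopifnot(category %in% names(profile))
  g <- ifelse(profile[[category]] >= threshold, high_label, low_label)
  names(g) <- profile$sample
  g
}

#' Overlap between two gene sets
#'
#' @param set_a,set_b [directed_gene_set()]s (direction ignored).
#' @return List: `fraction` = |A intersect B| / |A|, `jaccard` =
#'   |A intersect B| / |A union B|.
#' @export
signature_overlap <- function(set_a, set_b) {
  a <- names(set_a$weights); b <- names(set_b$weights)
  if (!length(a) || !length(b)) stop("gene sets must be nonempty")
  i <- length(intersect(a, b))
  list(fraction = i / length(a), jaccard = i / length(union(a, b)))
}

#' Read / write signed gene sets in extended GMT format
#'
#' Each line: set name, description, then `gene:+1` / `gene:-1` tokens.
#' Plain GMT tokens without a sign suffix are taken as +1.
#'
#' @param path file path.
#' @return `read_signed_gmt` returns a named list of [directed_gene_set()]s.
#' @export
read_signed_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    toks <- f[-(1:2)]
    sgn <- ifelse(grepl(":-1$", toks), -1, 1)
    genes <- sub(":[+-]?1$", "", toks)
    directed_gene_set(f[1], up = genes[sgn > 0], down = genes[sgn < 0],
                      provenance = f[2])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' @rdname read_signed_gmt
#' @param sets list of [directed_gene_set()]s.
#' @export
write_signed_gmt <- function(sets, path) {
  if (inherits(sets, "directed_gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    toks <- sprintf("%s:%+d", names(s$weights), s$weights)
    paste(c(s$name, s$provenance, toks), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write cohort scores as TSV (sample, score, n_used)
#' @param scores data.frame from [score_cohort()].
#' @param path output path.
#' @export
write_scores_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
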