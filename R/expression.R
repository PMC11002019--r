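# Count filtering, median-of-ratios normalization, NB Wald differential
# expression and multiple-testing adjustment. The DE test is a deliberate
# approximation: gene-wise method-of-moments dispersion, no shrinkage, Wald
# statistic on the log ratio of normalized group means.

#' Drop low-information genes
#'
#' A gene is kept iff its count exceeds `min_count` in strictly more than
#' `min_samples` samples; the sample set is unchanged.
#'
#' @param x an [expr_matrix()].
#' @param min_count count threshold (strict `>`).
#' @param min_samples sample-number threshold (strict `>`).
#' @return Filtered `expr_matrix`.
#' @export
filter_low_counts <- function(x, min_count = 20, min_samples = 5) {
  stopifnot(inherits(x, "expr_matrix"), min_count >= 0, min_samples >= 0)
  keep <- rowSums(x$counts > min_count) > min_samples
  expr_matrix(x$counts[keep, , drop = FALSE], x$size_factors)
}

#' Median-of-ratios size-factor normalization
#'
#' Size factor of a sample = median over reference genes (those with a
#' nonzero count in every sample) of count / geometric mean of that gene's
#' counts across samples.
#'
#' @param x an [expr_matrix()].
#' @return The matrix with `size_factors` filled in.
#' @export
median_of_ratios_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  m <- x$counts
  ref <- rowSums(m == 0) == 0
  if (!any(ref))
    stop("normalization error: no gene expressed in all samples; ",
         "consider a pseudo-reference fallback on a filtered matrix")
  logm <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- exp(apply(logm - loggeo, 2, stats::median))
  expr_matrix(m, sf)
}

#' Negative-binomial Wald differential expression
#'
#' Per gene: dispersion by pooled within-group method of moments on the
#' normalized counts (floored at 1e-8), log2 fold change of normalized group
#' means with pseudo-count 0.5, Wald z against the standard normal via the
#' delta method, BH-adjusted p across tested genes. `group_a` is the numerator
#' class (log2fc > 0 means up in `group_a`).
#'
#' @param x an [expr_matrix()]; normalized on the fly if needed.
#' @param group_a,group_b disjoint sample-id vectors, each of size >= 2.
#' @return data.frame: gene, log2fc, pvalue, padj, mean_a, mean_b.
#' @export
differential_expression <- function(x, group_a, group_b) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(intersect(group_a, group_b)))
    stop("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples")
  missing <- setdiff(c(group_a, group_b), colnames(x$counts))
  if (length(missing))
    stop("samples not in matrix: ", paste(missing, collapse = ", "))
  if (is.null(x$size_factors)) x <- median_of_ratios_normalize(x)
  y <- normalized_counts(x)
  a <- y[, group_a, drop = FALSE]
  b <- y[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  # pooled within-group moment dispersion: alpha = (var - mu) / mu^2
  disp_a <- (va - ma) / pmax(ma, 0.5)^2
  disp_b <- (vb - mb) / pmax(mb, 0.5)^2
  alpha <- pmax(((na - 1) * disp_a + (nb - 1) * disp_b) / (na + nb - 2), 1e-8)
  log2fc <- log2((ma + 0.5) / (mb + 0.5))
  # delta-method variance of log(mean) under NB mean-dispersion model
  v_log <- function(m, n) (pmax(m, 0.5) + alpha * pmax(m, 0.5)^2) /
    (n * pmax(m, 0.5)^2)
  se <- sqrt(v_log(ma, na) + v_log(mb, nb))
  z <- (log(ma + 0.5) - log(mb + 0.5)) / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(gene = rownames(y), log2fc = log2fc, pvalue = p,
             padj = stats::p.adjust(p, "BH"), mean_a = ma, mean_b = mb,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Multiple-testing adjustment: BH or two-stage BKY
#'
#' BH is the standard step-up false-discovery-rate adjustment. BKY is the
#' two-stage step-up: stage 1 runs BH at alpha' = alpha/(1+alpha) to estimate
#' the number of true nulls m0 = m - r1; stage 2 reports step-up adjusted
#' values p(i) * (1+alpha) * m0 / i, so that `adjusted <= alpha` reproduces
#' the two-stage rejection set at that fixed alpha.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method "BH" or "BKY".
#' @param alpha fixed level for the BKY two-stage estimate.
#' @return Adjusted values, input order preserved.
#' @export
adjust_pvalues <- function(p, method = c("BH", "BKY"), alpha = 0.05) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  if (method == "BH") return(stats::p.adjust(p, "BH"))
  m <- length(p)
  r1 <- sum(stats::p.adjust(p, "BH") <= alpha / (1 + alpha))
  m0 <- m - r1
  if (m0 == 0) return(rep(0, m))
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * (1 + alpha) * m0 / seq_len(m)))))
  q[order(o)]
}
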