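# Druggable-target matching: cross-match a patient's expressed and mutated
# genes against a drug-gene interaction table, filtered on category tags
# (e.g. approved / antineoplastic / immunotherapy).

#' Read a drug-gene interaction table
#'
#' TSV columns: gene, drug, interaction_type, categories (semicolon
#' separated tags).
#'
#' @param path TSV path. Defaults to the packaged synthetic snapshot.
#' @return data.frame with a list-column `categories`.
#' @export
read_drug_interactions <- function(path = system.file(
  "extdata", "drug_gene_interactions_synthetic.tsv", package = "melresist")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "drug", "interaction_type", "categories")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("interaction table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$categories <- strsplit(df$categories, ";", fixed = TRUE)
  df
}

#' Match druggable targets for one patient
#'
#' An interaction matches iff its gene is in the patient's expressed or
#' mutated set AND its category tags contain every required tag for that
#' basis. Tag requirements are configurable per basis, since
#' immunotherapy-style targets apply to expression while small-molecule
#' targets apply to mutations.
#'
#' @param patient patient identifier.
#' @param expressed_genes genes above the expression threshold (see
#'   [expressed_gene_sets()]).
#' @param mutated_genes genes mutated in the patient's filtered MAF.
#' @param interactions table from [read_drug_interactions()].
#' @param required_tags tags an expression-basis match must carry (all of
#'   them).
#' @param required_tags_mutation tags for mutation-basis matches (defaults
#'   to `required_tags`).
#' @return A `patient_target_profile`: patient, expressed/mutated sets, and
#'   `matched` (gene, drug, basis), sorted by gene then drug.
#' @export
match_druggable_targets <- function(patient, expressed_genes, mutated_genes,
                                    interactions,
                                    required_tags = c("approved",
                                                      "antineoplastic",
                                                      "immunotherapy"),
                                    required_tags_mutation = NULL) {
  if (is.null(required_tags_mutation)) required_tags_mutation <- required_tags
  if (!nrow(interactions)) {
    warning("empty interaction table: no matches possible")
    matched <- data.frame(gene = character(), drug = character(),
                          basis = character(), stringsAsFactors = FALSE)
  } else {
    has_tags <- function(tags) vapply(interactions$categories,
                                      function(cc) all(tags %in% cc),
                                      logical(1))
    expr_hit <- interactions$gene %in% expressed_genes & has_tags(required_tags)
    mut_hit <- interactions$gene %in% mutated_genes &
      has_tags(required_tags_mutation)
    matched <- rbind(
      data.frame(gene = interactions$gene[expr_hit],
                 drug = interactions$drug[expr_hit],
                 basis = rep("expression", sum(expr_hit)),
                 stringsAsFactors = FALSE),
      data.frame(gene = interactions$gene[mut_hit],
                 drug = interactions$drug[mut_hit],
                 basis = rep("mutation", sum(mut_hit)),
                 stringsAsFactors = FALSE))
    matched <- unique(matched)
    matched <- matched[order(matched$gene, matched$drug, matched$basis), ,
                       drop = FALSE]
    rownames(matched) <- NULL
  }
  structure(list(patient = patient,
                 expressed_genes = unique(expressed_genes),
                 mutated_genes = unique(mutated_genes),
                 matched = matched),
            class = "patient_target_profile")
}

#' @export
print.patient_target_profile <- function(x, ...) {
  cat(sprintf("patient_target_profile '%s': %d matches (%d expressed, %d mutated genes)\n",
              x$patient, nrow(x$matched), length(x$expressed_genes),
              length(x$mutated_genes)))
  invisible(x)
}

#' Per-sample expressed-gene sets by cohort upper-quartile threshold
#'
#' A gene counts as expressed in a sample when its normalized value strictly
#' exceeds the cohort quantile (default upper quartile) of that gene.
#'
#' @param x an [expr_matrix()] with size factors (normalized on the fly
#'   otherwise).
#' @param prob quantile threshold.
#' @return Named list: sample -> character vector of expressed genes.
#' @export
expressed_gene_sets <- function(x, prob = 0.75) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(x$size_factors)) x <- median_of_ratios_normalize(x)
  m <- normalized_counts(x)
  thr <- apply(m, 1, stats::quantile, probs = prob)
  sets <- lapply(colnames(m), function(s) rownames(m)[m[, s] > thr])
  names(sets) <- colnames(m)
  sets
}

#' Summarize matches for Sankey-style aggregation
#'
#' @param profiles list of `patient_target_profile`s.
#' @param groups named character: patient -> group label.
#' @return data.frame: group, gene, drug, basis, weight (patients matched).
#' @export
summarize_drug_matches <- function(profiles, groups) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    if (!nrow(p$matched)) return(NULL)
    cbind(group = unname(groups[p$patient]), p$matched,
          stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    return(data.frame(group = character(), gene = character(),
                      drug = character(), basis = character(),
                      weight = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(weight = rep(1L, nrow(rows))),
                          rows[c("group", "gene", "drug", "basis")], sum)
  agg[order(agg$group, agg$gene, agg$drug), , drop = FALSE]
}
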