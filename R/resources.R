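# Packaged editable resources: immunophenogram marker lists and comparator
# signature gene sets. These are curated placeholders shipped as plain text
# so users can swap in their own versions (the canonical lists live in
# external supplements and databases).

#' Immunophenogram category marker lists
#'
#' Reads the packaged category -> marker-gene table (editable TSV with
#' columns `category`, `gene`): effector cells, suppressor cells,
#' checkpoints and MHC.
#'
#' @param path TSV path; defaults to the packaged resource.
#' @return Named list: category -> gene vector.
#' @export
immunophenogram_categories <- function(path = system.file(
  "extdata", "immunophenogram_categories.tsv", package = "melresist")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(df$gene, df$category)
}

#' Packaged comparator signatures (synthetic placeholders)
#'
#' Loads the shipped signed GMT of comparator gene sets: an IPRES-style
#' equal-weight (+1) resistance set and the IMMU composite components
#' (effector components to be weighted +1, suppressive components -1).
#' These are synthetic placeholder lists; replace with user-supplied GMT
#' files for real analyses.
#'
#' @param path signed-GMT path; defaults to the packaged resource.
#' @return Named list of [directed_gene_set()]s.
#' @export
comparator_signatures <- function(path = system.file(
  "extdata", "comparator_signatures_synthetic.gmt", package = "melresist")) {
  read_signed_gmt(path)
}

#' Assemble the IMMU-style composite from component sets
#'
#' Effector components (chemokine, interferon-gamma, T effector, T-cell
#' inflamed) are pooled with weight +1; suppressive components
#' (beta-catenin, TGF-beta, immunosuppression) with weight -1.
#'
#' @param sets named list of component [directed_gene_set()]s (defaults to
#'   the packaged placeholders).
#' @return A merged [directed_gene_set()] named "IMMU".
#' @export
immu_composite <- function(sets = comparator_signatures()) {
  eff <- c("chemokine", "interferon_gamma", "t_effector", "t_cell_inflamed")
  sup <- c("b_catenin", "tgf_beta", "immunosuppression")
  missing <- setdiff(c(eff, sup), names(sets))
  if (length(missing))
    stop("missing IMMU component set(s): ", paste(missing, collapse = ", "))
  merge_directed_sets(sets[eff], sets[sup], name = "IMMU")
}
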