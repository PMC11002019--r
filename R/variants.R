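# Somatic-variant filter cascade and MAF emission.
#
# The cascade mirrors the post-calling filters of a duplex UMI amplicon
# pipeline. A record is kept iff it satisfies every applicable rule; the
# unique-alt-observation / duplex rules and the sequence-direction bias
# probability rule are waived for TERT-promoter records, and the
# caller-specific rules apply only to calls made by that caller. Dropped
# records are attributed to the first failing rule in the printed order.

#' Filter-cascade thresholds
#'
#' Defaults mirror the published rule set: (1) UDP > 10, UAO > 6 and DAO > 1
#' (UAO/DAO waived for TERT promoter); (2) homopolymer count < 6;
#' (3) gnomAD AD < 0.01 and global AF < 0.01; (4) no positive sequencing
#' direction or sample strand bias call; (5) sequence direction strand bias
#' probability > 0.1 (waived for TERT promoter); (6) FreeBayes calls:
#' (sample strand bias probability > 0.05 or ratio > 0.4) and 95MDAF < 0.2;
#' (7) LoFreq calls: 0.1 < AF <= 0.2; (8) coding variants kept only with
#' HIGH/MODERATE impact, non-coding only with a 5' UTR or upstream-gene
#' consequence.
#'
#' @param ... named overrides of any default threshold.
#' @return Named list of thresholds.
#' @export
filter_thresholds <- function(...) {
  defaults <- list(
    udp_min = 10, uao_min = 6, dao_min = 1,
    homopolymer_max = 6,
    gnomad_ad_max = 0.01, global_af_max = 0.01,
    seq_dir_bias_prob_min = 0.1,
    fb_ssb_prob_min = 0.05, fb_ssb_ratio_min = 0.4, fb_mdaf95_max = 0.2,
    lofreq_af_min = 0.1, lofreq_af_max = 0.2,
    coding_impacts = c("HIGH", "MODERATE"),
    noncoding_consequences = c("5_prime_UTR_variant", "upstream_gene_variant"))
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown)) stop("unknown threshold: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, ov)
}

REQUIRED_VARIANT_FIELDS <- c(
  "gene", "chrom", "pos", "ref", "alt", "caller", "UDP", "UAO", "DAO", "AF",
  "homopolymer_count", "gnomad_ad", "global_af", "seq_dir_bias_flag",
  "sample_strand_bias_flag", "seq_dir_bias_prob", "sample_strand_bias_prob",
  "sample_strand_bias_ratio", "mdaf95", "impact", "consequence",
  "is_tert_promoter")

validate_variant_records <- function(records) {
  miss <- setdiff(REQUIRED_VARIANT_FIELDS, names(records))
  if (length(miss))
    stop("variant records missing field(s): ", paste(miss, collapse = ", "))
  prob_fields <- c("AF", "gnomad_ad", "global_af", "seq_dir_bias_prob",
                   "sample_strand_bias_prob", "sample_strand_bias_ratio",
                   "mdaf95")
  for (f in prob_fields) {
    bad <- which(records[[f]] < 0 | records[[f]] > 1 | is.na(records[[f]]))
    if (length(bad))
      stop(sprintf("record %d: field '%s' outside [0, 1]", bad[1], f))
  }
  for (f in c("UDP", "UAO", "DAO", "homopolymer_count")) {
    bad <- which(records[[f]] < 0 | is.na(records[[f]]))
    if (length(bad))
      stop(sprintf("record %d: field '%s' must be a count >= 0", bad[1], f))
  }
  bad <- which(records$pos < 1)
  if (length(bad)) stop(sprintf("record %d: pos must be >= 1", bad[1]))
  invisible(records)
}

# n x 8 logical matrix of per-rule pass (TRUE where a rule does not apply)
variant_rule_matrix <- function(records, th = filter_thresholds()) {
  tert <- records$is_tert_promoter
  fb <- records$caller == "FreeBayes"
  lf <- records$caller == "LoFreq"
  cbind(
    r1 = records$UDP > th$udp_min &
      (tert | (records$UAO > th$uao_min & records$DAO > th$dao_min)),
    r2 = records$homopolymer_count < th$homopolymer_max,
    r3 = records$gnomad_ad < th$gnomad_ad_max &
      records$global_af < th$global_af_max,
    r4 = !records$seq_dir_bias_flag & !records$sample_strand_bias_flag,
    r5 = tert | records$seq_dir_bias_prob > th$seq_dir_bias_prob_min,
    r6 = !fb | ((records$sample_strand_bias_prob > th$fb_ssb_prob_min |
                   records$sample_strand_bias_ratio > th$fb_ssb_ratio_min) &
                  records$mdaf95 < th$fb_mdaf95_max),
    r7 = !lf | (records$AF > th$lofreq_af_min & records$AF <= th$lofreq_af_max),
    r8 = records$impact %in% th$coding_impacts |
      records$consequence %in% th$noncoding_consequences)
}

#' Apply the somatic-variant filter cascade
#'
#' @param records data.frame of variant records (see
#'   [generate_variant_records()] for the field set).
#' @param thresholds a [filter_thresholds()] list.
#' @return A `filter_report`: `kept` (data.frame), `dropped_by_rule` (named
#'   counts for rules 1-8, first-failure attribution), `input_count`, and a
#'   `rule_pass` matrix.
#' @export
apply_filter_cascade <- function(records, thresholds = filter_thresholds()) {
  validate_variant_records(records)
  pass <- variant_rule_matrix(records, thresholds)
  keep <- rowSums(!pass) == 0
  first_fail <- if (nrow(records)) {
    vapply(seq_len(nrow(records)), function(i) {
      fails <- which(!pass[i, ])
      if (length(fails)) fails[[1]] else NA_integer_
    }, integer(1))
  } else integer(0)
  dropped <- table(factor(first_fail[!keep], levels = 1:8))
  names(dropped) <- paste0("rule", 1:8)
  structure(list(kept = records[keep, , drop = FALSE],
                 dropped_by_rule = as.integer(dropped),
                 input_count = nrow(records),
                 rule_pass = pass,
                 first_fail = first_fail),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d in, %d kept\n", x$input_count, nrow(x$kept)))
  d <- x$dropped_by_rule
  for (i in 1:8) if (d[i] > 0) cat(sprintf("  rule %d dropped %d\n", i, d[i]))
  invisible(x)
}

# sequence-ontology consequence -> MAF Variant_Classification
maf_classification <- function(consequence) {
  map <- c(missense_variant = "Missense_Mutation",
           synonymous_variant = "Silent",
           stop_gained = "Nonsense_Mutation",
           stop_lost = "Nonstop_Mutation",
           frameshift_variant = "Frame_Shift_Del",
           inframe_deletion = "In_Frame_Del",
           inframe_insertion = "In_Frame_Ins",
           splice_acceptor_variant = "Splice_Site",
           splice_donor_variant = "Splice_Site",
           `5_prime_UTR_variant` = "5'UTR",
           `3_prime_UTR_variant` = "3'UTR",
           upstream_gene_variant = "5'Flank",
           intron_variant = "Intron")
  out <- unname(map[consequence])
  ifelse(is.na(out), consequence, out)
}

MAF_COLUMNS <- c("Hugo_Symbol", "Chromosome", "Start_Position", "End_Position",
                 "Reference_Allele", "Tumor_Seq_Allele2",
                 "Variant_Classification", "Tumor_Sample_Barcode")

#' Emit kept variants as MAF rows
#'
#' One row per kept record with the standard required columns; 1-based
#' inclusive coordinates. Records without a gene symbol are emitted as
#' "Unknown" with a warning.
#'
#' @param report a `filter_report` from [apply_filter_cascade()].
#' @param sample_id tumor sample barcode.
#' @param path optional path; when given the rows are written as TSV.
#' @return data.frame of MAF rows (header-only when nothing was kept).
#' @export
write_maf <- function(report, sample_id, path = NULL) {
  stopifnot(inherits(report, "filter_report"))
  k <- report$kept
  if (nrow(k)) {
    gene <- k$gene
    if (any(is.na(gene) | !nzchar(gene))) {
      warning("kept record(s) without gene symbol emitted as 'Unknown'")
      gene[is.na(gene) | !nzchar(gene)] <- "Unknown"
    }
    maf <- data.frame(
      Hugo_Symbol = gene,
      Chromosome = k$chrom,
      Start_Position = k$pos,
      End_Position = k$pos + pmax(nchar(k$ref) - 1L, 0L),
      Reference_Allele = k$ref,
      Tumor_Seq_Allele2 = k$alt,
      Variant_Classification = maf_classification(k$consequence),
      Tumor_Sample_Barcode = sample_id,
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    maf <- as.data.frame(matrix(character(0), 0, length(MAF_COLUMNS),
                                dimnames = list(NULL, MAF_COLUMNS)),
                         stringsAsFactors = FALSE)
  }
  if (!is.null(path))
    utils::write.table(maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  maf
}

#' Read a MAF file written by [write_maf()]
#' @param path file path.
#' @return data.frame of MAF rows.
#' @export
read_maf <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(Chromosome = "character",
                                   Reference_Allele = "character",
                                   Tumor_Seq_Allele2 = "character"))
}

#' Sample-level mutation co-occurrence of two genes
#'
#' Builds the 2x2 presence/absence table over the cohort and runs the exact
#' test; the odds ratio uses the Haldane +0.5 correction when any cell is 0.
#' A gene absent from the MAF entirely yields a zero row, not an error.
#'
#' @param maf MAF rows (multi-sample: distinguished by Tumor_Sample_Barcode).
#' @param gene_a,gene_b gene symbols.
#' @param cohort character vector of all sample barcodes (mutated or not).
#' @return List: `odds_ratio`, `p_value`, `table`.
#' @export
mutation_cooccurrence <- function(maf, gene_a, gene_b, cohort) {
  if (!length(cohort)) stop("cohort must contain at least one sample")
  has <- function(g) cohort %in%
    unique(maf$Tumor_Sample_Barcode[maf$Hugo_Symbol == g])
  a <- has(gene_a); b <- has(gene_b)
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                2, 2, byrow = TRUE,
                dimnames = list(c("a_mut", "a_wt"), c("b_mut", "b_wt")))
  or <- if (any(tab == 0)) {
    ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  } else (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p_value = as.numeric(fisher_exact(tab)), table = tab)
}

#' Read / write the flat variant-record TSV
#' @param path file path.
#' @return `read_variant_tsv` returns a validated records data.frame.
#' @export
read_variant_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  for (f in c("seq_dir_bias_flag", "sample_strand_bias_flag", "is_tert_promoter"))
    df[[f]] <- as.logical(df[[f]])
  validate_variant_records(df)
  df
}

#' @rdname read_variant_tsv
#' @param records variant records data.frame.
#' @export
write_variant_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal VCF ingestion into the variant-record table
#'
#' Reads CHROM/POS/REF/ALT plus INFO keys and maps them onto the record
#' fields via a configurable name map; fields missing from INFO take the
#' given defaults. TERT-promoter membership can be derived from a genomic
#' interval instead of an INFO flag. Requires the `vcfR` package.
#'
#' @param path VCF path.
#' @param info_map named character: record field -> INFO key.
#' @param defaults named list of values for fields absent from INFO.
#' @param tert_interval optional `list(chrom=, start=, end=)`; records inside
#'   it are flagged `is_tert_promoter`.
#' @return Validated variant-record data.frame.
#' @export
read_variants_vcf <- function(path, info_map = NULL, defaults = list(),
                              tert_interval = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_variants_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::INFO2df(v)
  df <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                   ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  if (is.null(info_map)) {
    shared <- intersect(REQUIRED_VARIANT_FIELDS, names(info))
    info_map <- stats::setNames(shared, shared)
  }
  for (field in names(info_map)) {
    key <- info_map[[field]]
    if (key %in% names(info)) df[[field]] <- info[[key]]
  }
  template <- generate_variant_records(1)[1, ]
  for (f in setdiff(REQUIRED_VARIANT_FIELDS, names(df))) {
    df[[f]] <- if (f %in% names(defaults)) defaults[[f]] else template[[f]]
  }
  for (f in c("UDP", "UAO", "DAO", "AF", "homopolymer_count", "gnomad_ad",
              "global_af", "seq_dir_bias_prob", "sample_strand_bias_prob",
              "sample_strand_bias_ratio", "mdaf95"))
    df[[f]] <- as.numeric(df[[f]])
  for (f in c("seq_dir_bias_flag", "sample_strand_bias_flag", "is_tert_promoter"))
    df[[f]] <- as.logical(df[[f]])
  if (!is.null(tert_interval))
    df$is_tert_promoter <- df$chrom == tert_interval$chrom &
      df$pos >= tert_interval$start & df$pos <= tert_interval$end
  validate_variant_records(df)
  df
}
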