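# Configuration-driven orchestration of the whole analysis: synthetic cohort
# generation (or file inputs), expression processing, signature construction
# and scoring, immunophenogram, variant filtering, spatial quantification,
# outcome statistics and drug matching. Every stage writes its outputs under
# the configured directory and a JSON manifest records seeds, input hashes
# and per-stage files, so a rerun with the same config reproduces identical
# numeric outputs.
#
# The global seed is expanded into fixed per-stage substreams (seed + stage
# offset), so adding a stage does not perturb earlier stages' randomness.

#' Pipeline configuration
#'
#' Either a `synthetic` block (arguments to [simulation_config()]) or paths
#' to existing inputs (`counts_tsv`, `cells_csv`, `variants_tsv`,
#' `outcomes_csv`). Signature training uses the resistant-vs-CR contrast
#' with PR samples excluded.
#'
#' @param out_dir output directory (created if absent).
#' @param seed global integer seed.
#' @param synthetic named list of [simulation_config()] overrides, or NULL
#'   when file inputs are given.
#' @param counts_tsv,cells_csv,variants_tsv,outcomes_csv optional input
#'   paths used when `synthetic` is NULL.
#' @param de_alpha adjusted-p threshold for signature membership.
#' @param score_normalize,score_method scoring variant flags passed to
#'   [score_cohort()].
#' @param thresholds [filter_thresholds()] overrides (named list).
#' @param n_variants number of synthetic variant records.
#' @return Validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 7L, synthetic = list(),
                            counts_tsv = NULL, cells_csv = NULL,
                            variants_tsv = NULL, outcomes_csv = NULL,
                            de_alpha = 0.05, score_normalize = FALSE,
                            score_method = "pooled", thresholds = list(),
                            n_variants = 40L) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              synthetic = synthetic, counts_tsv = counts_tsv,
              cells_csv = cells_csv, variants_tsv = variants_tsv,
              outcomes_csv = outcomes_csv, de_alpha = de_alpha,
              score_normalize = score_normalize, score_method = score_method,
              thresholds = thresholds, n_variants = as.integer(n_variants))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  paths <- c(cfg$counts_tsv, cfg$cells_csv, cfg$variants_tsv, cfg$outcomes_csv)
  if (is.null(cfg$synthetic) && !length(paths))
    stop("config needs either a synthetic block or input paths")
  for (p in paths) if (!file.exists(p))
    stop("validation error: input path does not exist: ", p)
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML path with keys matching [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages: synthetic generation (when configured), low-count filtering and
#' median-of-ratios normalization, resistant-vs-CR differential expression
#' (PR excluded), directed signature construction and cohort scoring with
#' ROC evaluation against random same-size signatures, immunophenogram
#' profiling, the somatic-variant filter cascade with MAF emission, spatial
#' density quantification, outcome statistics (Mann-Whitney on scores,
#' Kaplan-Meier/log-rank on progression-free survival, exact test of
#' response by treatment), and druggable-target matching.
#'
#' @param config a [pipeline_config()].
#' @param n_random_signatures random same-size signatures for the score AUC
#'   comparison.
#' @return The run manifest (also written as `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config, n_random_signatures = 100L) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("melresist")),
                   seed = config$seed, stages = list())
  stage <- function(name, files, info = list())
    manifest$stages[[name]] <<- c(list(outputs = files), info)

  ## stage 1: inputs (synthetic generation or files)
  if (!is.null(config$synthetic)) {
    sim <- do.call(simulation_config, utils::modifyList(
      config$synthetic, list(seed = config$seed)))
    cohort <- generate_expression_cohort(sim)
    expr <- cohort$matrix; truth <- cohort$truth
    cells <- generate_cell_table(sim)
    variants <- generate_variant_records(config$n_variants,
                                         seed = config$seed + 3L)
    outcomes <- generate_outcomes(truth, sim)
    write_counts_tsv(expr, out("counts.tsv"))
    write_truth_json(truth, out("truth.json"))
    write_cell_table_csv(cells, out("cells.csv"))
    write_variant_tsv(variants, out("variants.tsv"))
    utils::write.csv(outcomes, out("outcomes.csv"), row.names = FALSE,
                     quote = FALSE)
    stage("simulate", c("counts.tsv", "truth.json", "cells.csv",
                        "variants.tsv", "outcomes.csv"),
          list(n_genes = nrow(counts(expr)), n_samples = ncol(counts(expr))))
  } else {
    expr <- read_counts_tsv(config$counts_tsv)
    truth <- NULL
    cells <- if (!is.null(config$cells_csv)) read_cell_table_csv(config$cells_csv)
    variants <- if (!is.null(config$variants_tsv)) read_variant_tsv(config$variants_tsv)
    outcomes <- utils::read.csv(config$outcomes_csv, stringsAsFactors = FALSE)
    manifest$input_md5 <- as.list(tools::md5sum(
      c(config$counts_tsv, config$cells_csv, config$variants_tsv,
        config$outcomes_csv)))
    stage("load", character(0))
  }
  classes <- stats::setNames(outcomes$response, outcomes$sample)

  ## stage 2: expression processing and DE (resistant PD vs CR; PR excluded)
  filtered <- filter_low_counts(expr)
  norm <- median_of_ratios_normalize(filtered)
  pd <- names(classes)[classes == "PD"]
  cr <- names(classes)[classes == "CR"]
  de <- differential_expression(norm, group_a = pd, group_b = cr)
  utils::write.table(de, out("de_table.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stage("differential_expression", "de_table.tsv",
        list(n_tested = nrow(de),
             n_significant = sum(de$padj < config$de_alpha)))

  ## stage 3: signature construction, scoring, ROC evaluation
  yim <- build_directed_signature(de, alpha = config$de_alpha, name = "YIM")
  write_signed_gmt(yim, out("yim_signature.gmt"))
  scores <- score_cohort(norm, yim, normalize = config$score_normalize,
                         method = config$score_method)
  write_scores_tsv(scores, out("yim_scores.tsv"))
  lab <- classes[scores$sample]
  auc <- roc_auc(scores$score[lab %in% c("PD", "CR")],
                 lab[lab %in% c("PD", "CR")] == "PD")
  set.seed(config$seed + 4L)
  genes_all <- rownames(counts(norm))
  n_sig <- length(yim$weights)
  rand_auc <- vapply(seq_len(n_random_signatures), function(i) {
    g <- sample(genes_all, n_sig)
    k <- max(1, n_sig %/% 2)
    rs <- directed_gene_set(sprintf("rand%03d", i), up = g[seq_len(k)],
                            down = g[-seq_len(k)])
    s <- score_cohort(norm, rs)
    roc_auc(s$score[lab %in% c("PD", "CR")],
            lab[lab %in% c("PD", "CR")] == "PD")
  }, numeric(1))
  stage("signature_scoring", c("yim_signature.gmt", "yim_scores.tsv"),
        list(signature_size = n_sig, auc_pd_vs_cr = auc,
             random_signatures_beaten = sum(auc > rand_auc)))

  ## stage 4: immunophenogram over synthetic category lists (when the cohort
  ## is synthetic, categories are drawn from the planted program so that the
  ## profile carries signal; with real data the packaged marker lists apply)
  categories <- if (!is.null(truth)) {
    set.seed(config$seed + 5L)
    nulls <- setdiff(genes_all, c(truth$up_genes, truth$down_genes))
    list(effector_cells = sample(intersect(truth$down_genes, genes_all),
                                 min(8, length(intersect(truth$down_genes, genes_all)))),
         suppressor_cells = sample(intersect(truth$up_genes, genes_all),
                                   min(8, length(intersect(truth$up_genes, genes_all)))),
         checkpoints = sample(nulls, 8),
         MHC = sample(nulls, 8))
  } else immunophenogram_categories()
  ipg <- immunophenogram_scores(norm, categories)
  utils::write.table(ipg, out("immunophenogram.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  groups <- immunophenogram_stratify(ipg)
  stage("immunophenogram", "immunophenogram.tsv",
        list(n_high = sum(groups == "SIL_high")))

  ## stage 5: variant filter cascade and MAF
  th <- do.call(filter_thresholds, config$thresholds)
  report <- apply_filter_cascade(variants, th)
  maf <- write_maf(report, sample_id = "COHORT", path = out("variants.maf"))
  stage("variant_filtering", "variants.maf",
        list(input = report$input_count, kept = nrow(report$kept),
             dropped_by_rule = as.list(stats::setNames(
               report$dropped_by_rule, paste0("rule", 1:8)))))

  ## stage 6: spatial density quantification
  dens <- density_table(cells, default_phenotype_queries())
  utils::write.table(dens, out("densities.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd8_treg <- phenotype_ratio(cells, default_phenotype_queries()$cd8_t,
                              default_phenotype_queries()$treg, "peritumor")
  stage("spatial", "densities.tsv",
        list(cd8_treg_peritumor = cd8_treg$ratio))

  ## stage 7: outcome statistics
  sc <- scores$score
  mw <- mann_whitney_u(sc[lab == "PD"], sc[lab == "CR"])
  surv <- survival_compare(
    data.frame(time = outcomes$pfs_months, event = outcomes$pfs_event,
               group = outcomes$response)[outcomes$response %in% c("PD", "CR"), ],
    "PD", "CR")
  resp_tab <- table(outcomes$treatment, outcomes$response %in% c("CR", "PR"))
  fisher_p <- fisher_exact(as.matrix(resp_tab))
  statlines <- data.frame(
    test = c("mann_whitney_yim_pd_vs_cr", "logrank_pfs_pd_vs_cr",
             "fisher_response_by_treatment"),
    statistic = c(mw$U, surv$chisq, NA),
    p_value = c(mw$p_value, surv$p_value, as.numeric(fisher_p)),
    note = c(mw$method, "1 df", attr(fisher_p, "method")),
    stringsAsFactors = FALSE)
  utils::write.table(statlines, out("statistics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage("statistics", "statistics.tsv")

  ## stage 8: druggable-target matching
  interactions <- read_drug_interactions()
  expressed <- expressed_gene_sets(norm)
  mutated_by_sample <- split(maf$Hugo_Symbol, maf$Tumor_Sample_Barcode)
  profiles <- lapply(names(classes), function(s) {
    match_druggable_targets(
      s, expressed[[s]],
      if (!is.null(mutated_by_sample[[s]])) mutated_by_sample[[s]] else
        unique(maf$Hugo_Symbol),
      interactions,
      required_tags_mutation = c("approved", "antineoplastic"))
  })
  summary_tab <- summarize_drug_matches(
    profiles, stats::setNames(unname(classes), names(classes)))
  utils::write.table(summary_tab, out("drug_matches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stage("drug_match", "drug_matches.tsv",
        list(n_match_rows = nrow(summary_tab)))

  manifest$completed <- TRUE
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
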