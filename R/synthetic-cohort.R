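# Synthetic cohort generator: negative-binomial counts with a planted
# resistance expression program, spatial cell point patterns, variant records
# spanning the filter cascade, and exponential survival outcomes. The
# generator encodes the cohort structure the downstream analyses assume
# (PD-like resistant, CR-like responder, PR intermediate), so every stage can
# be tested end to end without patient data.

#' Markers recorded per segmented cell
#' @keywords internal
MIF_MARKERS <- c("CD3", "CD8", "FOXP3", "ICOS", "CD39", "PD1", "GZMB", "SOX10")

# phenotype -> marker-flag template used by the cell generator
phenotype_marker_template <- function() {
  tmpl <- list(
    tumor     = c("SOX10"),
    t_helper  = c("CD3"),
    cd8_t     = c("CD3", "CD8", "GZMB"),
    treg      = c("CD3", "FOXP3"),
    treg_icos = c("CD3", "FOXP3", "ICOS", "CD39")
  )
  lapply(tmpl, function(m) as.integer(MIF_MARKERS %in% m))
}

#' Default expected cell intensities (cells per mm^2)
#'
#' Peritumoral T-cell enrichment relative to the tumor core mirrors the
#' stroma-infiltrating lymphocyte pattern of ICI-resistant melanoma.
#' @return Named list: phenotype -> named numeric of per-region intensities.
#' @export
default_cell_intensities <- function() {
  list(
    tumor     = c(intratumor = 2000, peritumor = 100),
    t_helper  = c(intratumor = 200,  peritumor = 400),
    cd8_t     = c(intratumor = 150,  peritumor = 250),
    treg      = c(intratumor = 50,   peritumor = 150),
    treg_icos = c(intratumor = 20,   peritumor = 60)
  )
}

#' Simulation configuration for the synthetic cohort
#'
#' @param n_per_group samples per outcome class (resistant PD, CR, PR).
#' @param n_genes total genes simulated.
#' @param n_signature_genes planted resistance-program genes (half up in the
#'   resistant class, half up in CR).
#' @param log2_effect planted log2 fold change between resistant and CR
#'   classes; PR samples receive half the effect.
#' @param nb_dispersion negative-binomial dispersion alpha, shared across
#'   genes; variance = mu + alpha * mu^2.
#' @param baseline_mean expected count of a typical gene; per-gene baselines
#'   are drawn log-normally around it (`gene_mean_sdlog`).
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @param cell_intensities phenotype -> region -> expected cells per mm^2.
#' @param region_areas named region areas in mm^2 (> 0).
#' @param hazard_by_group per-class progression hazard, events per month.
#' @param censor_rate exponential censoring hazard (0 = no censoring).
#' @param gene_mean_sdlog log-normal sd of per-gene baseline means.
#' @param libsize_sdlog log-normal sd of per-sample library-size factors.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_per_group = 24,
                              n_genes = 2000,
                              n_signature_genes = 100,
                              log2_effect = 1.5,
                              nb_dispersion = 0.1,
                              baseline_mean = 100,
                              seed = 1L,
                              cell_intensities = default_cell_intensities(),
                              region_areas = c(intratumor = 2, peritumor = 1),
                              hazard_by_group = c(PD = 0.20, PR = 0.10, CR = 0.04),
                              censor_rate = 0.02,
                              gene_mean_sdlog = 1,
                              libsize_sdlog = 0.2) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_genes = as.integer(n_genes),
              n_signature_genes = as.integer(n_signature_genes),
              log2_effect = log2_effect,
              nb_dispersion = nb_dispersion,
              baseline_mean = baseline_mean,
              seed = as.integer(seed),
              cell_intensities = cell_intensities,
              region_areas = region_areas,
              hazard_by_group = hazard_by_group,
              censor_rate = censor_rate,
              gene_mean_sdlog = gene_mean_sdlog,
              libsize_sdlog = libsize_sdlog)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why)
    stop(sprintf("invalid configuration: field '%s' %s", field, why), call. = FALSE)
  if (cfg$n_per_group < 1) bad("n_per_group", "must be >= 1")
  if (cfg$n_genes < 1) bad("n_genes", "must be >= 1")
  if (cfg$n_signature_genes < 0 || cfg$n_signature_genes > cfg$n_genes)
    bad("n_signature_genes", "must be between 0 and n_genes")
  if (!is.finite(cfg$nb_dispersion) || cfg$nb_dispersion <= 0)
    bad("nb_dispersion", "must be > 0")
  if (cfg$baseline_mean <= 0) bad("baseline_mean", "must be > 0")
  if (any(cfg$region_areas <= 0)) bad("region_areas", "must all be > 0")
  if (is.null(names(cfg$region_areas))) bad("region_areas", "must be named")
  if (any(cfg$hazard_by_group <= 0)) bad("hazard_by_group", "rates must be > 0")
  if (!all(c("PD", "CR", "PR") %in% names(cfg$hazard_by_group)))
    bad("hazard_by_group", "must name classes PD, CR and PR")
  for (ph in names(cfg$cell_intensities)) {
    ints <- cfg$cell_intensities[[ph]]
    if (any(ints < 0)) bad("cell_intensities", sprintf("negative rate for '%s'", ph))
    unknown <- setdiff(names(ints), names(cfg$region_areas))
    if (length(unknown))
      bad("cell_intensities",
          sprintf("references unknown region '%s'", unknown[1]))
  }
  if (cfg$censor_rate < 0) bad("censor_rate", "must be >= 0")
  invisible(cfg)
}

#' Generate a synthetic expression cohort with a planted resistance program
#'
#' Counts are negative-binomial with per-gene log-normal baseline means and
#' per-sample log-normal library-size factors. A random subset of
#' `n_signature_genes` genes carries the planted program: half are shifted up
#' by `2^log2_effect` in the resistant (PD) class, half down; PR samples get
#' half the planted effect to mimic their intermediate biology.
#'
#' @param config a [simulation_config()].
#' @return List with `matrix` (an [expr_matrix()]) and `truth`
#'   (`up_genes`, `down_genes`, `class_labels`).
#' @export
generate_expression_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_per_group
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  samples <- c(sprintf("PD_%02d", seq_len(n)),
               sprintf("CR_%02d", seq_len(n)),
               sprintf("PR_%02d", seq_len(n)))
  classes <- rep(c("PD", "CR", "PR"), each = n)
  names(classes) <- samples

  mu_g <- stats::rlnorm(config$n_genes, meanlog = log(config$baseline_mean),
                        sdlog = config$gene_mean_sdlog)
  planted <- sample(genes, config$n_signature_genes)
  n_up <- ceiling(config$n_signature_genes / 2)
  up_genes <- planted[seq_len(n_up)]
  down_genes <- setdiff(planted, up_genes)

  lfc <- numeric(config$n_genes)
  names(lfc) <- genes
  lfc[up_genes] <- config$log2_effect
  lfc[down_genes] <- -config$log2_effect
  # per-class multiplicative effect on the mean (CR is the reference class)
  eff <- cbind(PD = 2^lfc, CR = rep(1, config$n_genes), PR = 2^(lfc / 2))

  libsize <- stats::rlnorm(length(samples), 0, config$libsize_sdlog)
  mu <- outer(mu_g, libsize) * eff[, classes]
  m <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
              nrow = config$n_genes, dimnames = list(genes, samples))
  truth <- list(up_genes = up_genes, down_genes = down_genes,
                class_labels = classes)
  list(matrix = expr_matrix(m), truth = truth)
}

#' Generate a synthetic segmented-cell table
#'
#' Each (phenotype, region) stratum is a homogeneous Poisson point pattern
#' with the configured intensity (cells/mm^2) times the region area.
#' Regions are disjoint squares; coordinates are in micrometres
#' (1 mm^2 = 1e6 um^2).
#'
#' @param config a [simulation_config()].
#' @return A [cell_table()] with marker flag columns and region areas.
#' @export
generate_cell_table <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  tmpl <- phenotype_marker_template()
  regions <- names(config$region_areas)
  side <- sqrt(config$region_areas) * 1000  # um
  # lay region squares left to right with a 500 um gap
  x0 <- c(0, cumsum(side + 500))[seq_along(regions)]
  names(x0) <- regions

  rows <- list()
  for (ph in names(config$cell_intensities)) {
    if (!ph %in% names(tmpl))
      stop(sprintf("invalid configuration: unknown phenotype '%s'", ph))
    ints <- config$cell_intensities[[ph]]
    for (rg in names(ints)) {
      k <- stats::rpois(1, ints[[rg]] * config$region_areas[[rg]])
      if (k == 0) next
      df <- data.frame(
        x_um = x0[[rg]] + stats::runif(k, 0, side[[rg]]),
        y_um = stats::runif(k, 0, side[[rg]]),
        region = rg, stringsAsFactors = FALSE)
      flags <- matrix(rep(tmpl[[ph]], each = k), nrow = k,
                      dimnames = list(NULL, MIF_MARKERS))
      rows[[length(rows) + 1L]] <- cbind(df, as.data.frame(flags))
    }
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(x_um = numeric(0), y_um = numeric(0),
                     region = character(0)),
          as.data.frame(matrix(integer(0), 0, length(MIF_MARKERS),
                               dimnames = list(NULL, MIF_MARKERS))))
  rownames(cells) <- NULL
  cell_table(cells, config$region_areas)
}

#' Generate synthetic annotated variant records
#'
#' A deterministic designed block of 20 records covers the pass and fail
#' branch of every filter rule — including TERT-promoter waivers and both
#' callers — and additional seeded random records are appended beyond 20.
#'
#' @param n number of records (>= 0).
#' @param seed integer seed.
#' @return data.frame of variant records, one per row.
#' @export
generate_variant_records <- function(n, seed = 1L) {
  stopifnot(n >= 0)
  base <- function(gene = "BRAF", chrom = "7", pos = 140453136,
                   ref = "A", alt = "T", caller = "FreeBayes",
                   UDP = 50, UAO = 20, DAO = 5, AF = 0.3,
                   homopolymer_count = 2, gnomad_ad = 1e-4, global_af = 5e-4,
                   seq_dir_bias_flag = FALSE, sample_strand_bias_flag = FALSE,
                   seq_dir_bias_prob = 0.5, sample_strand_bias_prob = 0.3,
                   sample_strand_bias_ratio = 0.5, mdaf95 = 0.05,
                   impact = "MODERATE", consequence = "missense_variant",
                   is_tert_promoter = FALSE) {
    data.frame(gene = gene, chrom = chrom, pos = pos, ref = ref, alt = alt,
               caller = caller, UDP = UDP, UAO = UAO, DAO = DAO, AF = AF,
               homopolymer_count = homopolymer_count, gnomad_ad = gnomad_ad,
               global_af = global_af, seq_dir_bias_flag = seq_dir_bias_flag,
               sample_strand_bias_flag = sample_strand_bias_flag,
               seq_dir_bias_prob = seq_dir_bias_prob,
               sample_strand_bias_prob = sample_strand_bias_prob,
               sample_strand_bias_ratio = sample_strand_bias_ratio,
               mdaf95 = mdaf95, impact = impact, consequence = consequence,
               is_tert_promoter = is_tert_promoter, stringsAsFactors = FALSE)
  }
  designed <- rbind(
    base(),                                                            # 1 pass, FreeBayes coding
    base(gene = "NRAS", chrom = "1", pos = 115258747, caller = "LoFreq",
         AF = 0.15),                                                   # 2 pass, LoFreq
    base(gene = "CDKN2A", chrom = "9", pos = 21974695, caller = "merged",
         impact = "MODIFIER", consequence = "5_prime_UTR_variant"),    # 3 pass, non-coding
    base(gene = "TERT", chrom = "5", pos = 1295228, caller = "merged",
         UAO = 2, DAO = 0, seq_dir_bias_prob = 0.05, impact = "MODIFIER",
         consequence = "upstream_gene_variant", is_tert_promoter = TRUE), # 4 pass via TERT waivers
    base(gene = "PTEN", chrom = "10", pos = 89692905, UDP = 5),        # 5 fail r1 (UDP)
    base(gene = "KIT", chrom = "4", pos = 55593464, UAO = 3),          # 6 fail r1 (UAO)
    base(gene = "TP53", chrom = "17", pos = 7577121, DAO = 1),         # 7 fail r1 (DAO)
    base(gene = "NF1", chrom = "17", pos = 29553485,
         homopolymer_count = 7),                                       # 8 fail r2
    base(gene = "KRAS", chrom = "12", pos = 25398284, gnomad_ad = 0.05), # 9 fail r3 (gnomAD)
    base(gene = "PIK3CA", chrom = "3", pos = 178936091,
         global_af = 0.02),                                            # 10 fail r3 (global AF)
    base(gene = "PREX2", chrom = "8", pos = 68864353,
         seq_dir_bias_flag = TRUE),                                    # 11 fail r4
    base(gene = "RAC1", chrom = "7", pos = 6426891,
         sample_strand_bias_flag = TRUE),                              # 12 fail r4
    base(gene = "IDH1", chrom = "2", pos = 209113112,
         seq_dir_bias_prob = 0.05),                                    # 13 fail r5
    base(gene = "ARID2", chrom = "12", pos = 46245653,
         sample_strand_bias_prob = 0.01, sample_strand_bias_ratio = 0.2), # 14 fail r6 (bias)
    base(gene = "MAP2K1", chrom = "15", pos = 66727455, mdaf95 = 0.3), # 15 fail r6 (95MDAF)
    base(gene = "DDX3X", chrom = "X", pos = 41203510, caller = "LoFreq",
         AF = 0.05),                                                   # 16 fail r7 (AF low)
    base(gene = "PPP6C", chrom = "9", pos = 127934021, caller = "LoFreq",
         AF = 0.5),                                                    # 17 fail r7 (AF high)
    base(gene = "SF3B1", chrom = "2", pos = 198266834, impact = "LOW",
         consequence = "synonymous_variant"),                          # 18 fail r8 (coding LOW)
    base(gene = "CTNNB1", chrom = "3", pos = 41265560, impact = "MODIFIER",
         consequence = "intron_variant"),                              # 19 fail r8 (non-coding)
    base(gene = "TERT", chrom = "5", pos = 1295250, caller = "LoFreq",
         AF = 0.15, UAO = 1, DAO = 0, impact = "MODIFIER",
         consequence = "upstream_gene_variant", is_tert_promoter = TRUE) # 20 pass, TERT + LoFreq
  )
  if (n <= nrow(designed)) return(designed[seq_len(n), , drop = FALSE])
  set.seed(seed)
  extra_n <- n - nrow(designed)
  extras <- do.call(rbind, lapply(seq_len(extra_n), function(i) {
    b <- base(gene = sprintf("GENE%03d", i), chrom = as.character(sample(1:22, 1)),
              pos = sample.int(2e8, 1),
              caller = sample(c("FreeBayes", "LoFreq", "merged"), 1),
              UDP = sample(0:100, 1), UAO = sample(0:40, 1),
              AF = stats::runif(1))
    b
  }))
  rownames(extras) <- NULL
  rbind(designed, extras)
}

#' Generate synthetic clinical outcomes linked to the planted classes
#'
#' Progression-free survival is exponential with the per-class hazard;
#' overall survival uses half that hazard. Censoring times are drawn
#' independently (exponential with `censor_rate`; none when the rate is 0).
#' Treatment assignment mirrors the cohort structure: responders are mostly
#' on combination ICI, resistant patients mostly on monotherapy.
#'
#' @param truth planted truth from [generate_expression_cohort()].
#' @param config a [simulation_config()].
#' @return data.frame: sample, response, treatment, pfs_months, pfs_event,
#'   os_months, os_event.
#' @export
generate_outcomes <- function(truth, config) {
  validate_sim_config(config)
  stopifnot(!is.null(truth$class_labels))
  set.seed(config$seed + 2L)
  cls <- truth$class_labels
  n <- length(cls)
  haz <- config$hazard_by_group[cls]
  surv_time <- function(rate) stats::rexp(n, rate)
  cens <- function() if (config$censor_rate > 0)
    stats::rexp(n, config$censor_rate) else rep(Inf, n)
  pfs_t <- surv_time(haz); pfs_c <- cens()
  os_t <- surv_time(haz / 2); os_c <- cens()
  p_combo <- c(PD = 0.3, PR = 0.5, CR = 0.8)[cls]
  treatment <- ifelse(stats::runif(n) < p_combo, "combination", "monotherapy")
  data.frame(
    sample = names(cls),
    response = unname(cls),
    treatment = treatment,
    pfs_months = pmin(pfs_t, pfs_c),
    pfs_event = as.integer(pfs_t <= pfs_c),
    os_months = pmin(os_t, os_c),
    os_event = as.integer(os_t <= os_c),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the planted truth as a JSON sidecar
#' @param truth planted truth list.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(up_genes = truth$up_genes, down_genes = truth$down_genes,
         class_labels = as.list(truth$class_labels)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
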