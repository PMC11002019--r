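# The 20-record fixture was traced by hand against the printed rule order:
# records 1-4 and 20 satisfy every applicable rule (2 of them via the TERT
# promoter waivers), and records 5-19 each fail exactly the rule they were
# designed to probe. The frozen partition below is that hand trace.
HAND_TRACE_KEPT <- c(1L, 2L, 3L, 4L, 20L)
HAND_TRACE_FIRST_FAIL <- c(
  `5` = 1L, `6` = 1L, `7` = 1L, `8` = 2L, `9` = 3L, `10` = 3L, `11` = 4L,
  `12` = 4L, `13` = 5L, `14` = 6L, `15` = 6L, `16` = 7L, `17` = 7L,
  `18` = 8L, `19` = 8L)

test_that("filter cascade reproduces the hand-traced partition of the fixture", {
  rec <- generate_variant_records(20, seed = 3)
  rep <- apply_filter_cascade(rec)
  expect_identical(which(seq_len(20) %in% as.integer(rownames(rep$kept))),
                   which(seq_len(20) %in% HAND_TRACE_KEPT))
  expect_identical(rep$first_fail[as.integer(names(HAND_TRACE_FIRST_FAIL))],
                   unname(HAND_TRACE_FIRST_FAIL))
  expect_identical(rep$input_count, 20L)
  expect_identical(nrow(rep$kept) + sum(rep$dropped_by_rule), 20L)
})

test_that("single-rule failures are attributed to the printed rule order", {
  rec <- generate_variant_records(1)
  rec$UDP <- 5
  rep <- apply_filter_cascade(rec)
  expect_identical(rep$first_fail[1], 1L)
  # a record failing rules 3 and 5 is attributed to rule 3 (first in order)
  rec2 <- generate_variant_records(1)
  rec2$gnomad_ad <- 0.5; rec2$seq_dir_bias_prob <- 0.01
  expect_identical(apply_filter_cascade(rec2)$first_fail[1], 3L)
})

test_that("TERT promoter waivers apply to rules 1 (UAO/DAO) and 5 only", {
  rec <- generate_variant_records(1)
  rec$UAO <- 2; rec$DAO <- 0; rec$seq_dir_bias_prob <- 0.05
  rec$impact <- "MODIFIER"; rec$consequence <- "upstream_gene_variant"
  expect_identical(nrow(apply_filter_cascade(rec)$kept), 0L)
  rec$is_tert_promoter <- TRUE
  expect_identical(nrow(apply_filter_cascade(rec)$kept), 1L)
  # UDP is not waived for TERT promoter records
  rec$UDP <- 5
  expect_identical(apply_filter_cascade(rec)$first_fail[1], 1L)
})

test_that("caller-specific rules bind only their caller", {
  rec <- generate_variant_records(1)   # FreeBayes template, AF = 0.3
  rec$caller <- "LoFreq"
  expect_identical(apply_filter_cascade(rec)$first_fail[1], 7L)
  rec$caller <- "merged"
  expect_identical(nrow(apply_filter_cascade(rec)$kept), 1L)
  rec$caller <- "FreeBayes"; rec$mdaf95 <- 0.9
  expect_identical(apply_filter_cascade(rec)$first_fail[1], 6L)
})

test_that("keep decision is conjunctive, idempotent and threshold-monotone", {
  rec <- generate_variant_records(60, seed = 9)
  rep <- apply_filter_cascade(rec)
  # conjunctive: keep set equals records passing every rule re-derived
  # independently of attribution order
  pass_all <- rowSums(!rep$rule_pass) == 0
  expect_identical(as.integer(rownames(rep$kept)), which(pass_all))
  # idempotent: filtering the kept set drops nothing
  rep2 <- apply_filter_cascade(rep$kept)
  expect_identical(nrow(rep2$kept), nrow(rep$kept))
  expect_true(all(rep2$dropped_by_rule == 0))
  # tightening any threshold never increases the kept count
  base_kept <- nrow(rep$kept)
  tighter <- list(list(udp_min = 60), list(uao_min = 30),
                  list(homopolymer_max = 1), list(gnomad_ad_max = 1e-6),
                  list(seq_dir_bias_prob_min = 0.9),
                  list(fb_mdaf95_max = 0.01),
                  list(lofreq_af_min = 0.19, lofreq_af_max = 0.2),
                  list(coding_impacts = "HIGH"))
  for (ov in tighter) {
    th <- do.call(filter_thresholds, ov)
    expect_lte(nrow(apply_filter_cascade(rec, th)$kept), base_kept)
  }
})

test_that("malformed records are rejected with their index", {
  rec <- generate_variant_records(3)
  rec$AF[2] <- 1.5
  expect_error(apply_filter_cascade(rec), "record 2.*AF")
  rec2 <- generate_variant_records(3)
  rec2$pos[3] <- 0
  expect_error(apply_filter_cascade(rec2), "record 3")
})

test_that("MAF emission writes standard columns and round-trips", {
  rec <- generate_variant_records(20, seed = 3)
  rep <- apply_filter_cascade(rec)
  tf <- tempfile(fileext = ".maf")
  maf <- write_maf(rep, "AYA_01", path = tf)
  expect_identical(nrow(maf), nrow(rep$kept))
  expect_true(all(c("Hugo_Symbol", "Chromosome", "Start_Position",
                    "Reference_Allele", "Tumor_Seq_Allele2",
                    "Variant_Classification", "Tumor_Sample_Barcode")
                  %in% names(maf)))
  back <- read_maf(tf)
  expect_equal(back$Hugo_Symbol, rep$kept$gene)
  expect_equal(back$Start_Position, rep$kept$pos)
  expect_equal(back$Chromosome, rep$kept$chrom)
  expect_equal(back$Reference_Allele, rep$kept$ref)
  expect_equal(back$Tumor_Seq_Allele2, rep$kept$alt)
  expect_true(all(back$Tumor_Sample_Barcode == "AYA_01"))
  # empty report -> header-only MAF; missing gene symbol -> Unknown + warning
  empty <- apply_filter_cascade(generate_variant_records(1)[0, ])
  expect_identical(nrow(write_maf(empty, "x")), 0L)
  one <- apply_filter_cascade(generate_variant_records(1))
  one$kept$gene <- ""
  expect_warning(maf1 <- write_maf(one, "x"), "Unknown")
  expect_identical(maf1$Hugo_Symbol, "Unknown")
})

test_that("variant TSV round-trips through the flat projection", {
  rec <- generate_variant_records(25, seed = 5)
  tf <- tempfile(fileext = ".tsv")
  write_variant_tsv(rec, tf)
  back <- read_variant_tsv(tf)
  expect_equal(back$UDP, rec$UDP)
  expect_equal(back$is_tert_promoter, rec$is_tert_promoter)
  expect_equal(back$chrom, rec$chrom)
  expect_identical(nrow(apply_filter_cascade(back)$kept),
                   nrow(apply_filter_cascade(rec)$kept))
})

test_that("mutation co-occurrence builds the sample-level 2x2 and delegates to the exact test", {
  maf <- data.frame(
    Hugo_Symbol = c("TERT", "BRAF", "TERT", "BRAF", "TERT", "BRAF", "KIT"),
    Tumor_Sample_Barcode = c("s1", "s1", "s2", "s2", "s3", "s3", "s4"))
  cohort <- sprintf("s%d", 1:8)
  res <- mutation_cooccurrence(maf, "TERT", "BRAF", cohort)
  expect_identical(unname(res$table[1, 1]), 3L)   # perfect co-occurrence
  expect_gt(res$odds_ratio, 1)
  expect_equal(res$p_value, oracle_fisher_2x2(matrix(c(3, 0, 0, 5), 2)),
               tolerance = 1e-12)
  # [[1,1],[1,1]] -> P = 1
  maf2 <- data.frame(Hugo_Symbol = c("A", "B"),
                     Tumor_Sample_Barcode = c("s1", "s2"))
  res2 <- mutation_cooccurrence(maf2, "A", "B", sprintf("s%d", 1:4))
  expect_equal(as.numeric(res2$p_value), 1)
  # gene absent from the MAF -> zero row (degenerate table warns, P = 1)
  expect_warning(
    res3 <- mutation_cooccurrence(maf2, "ZZZ", "B", sprintf("s%d", 1:4)),
    "zero")
  expect_identical(sum(res3$table[1, ]), 0L)
  expect_equal(res3$p_value, 1)
})
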