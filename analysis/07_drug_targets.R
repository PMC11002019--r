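#!/usr/bin/env Rscript
# Stage 7: cross-match expressed and mutated genes against the packaged
# drug-gene interaction snapshot. Expression-basis matches require the full
# approved/antineoplastic/immunotherapy tag set; mutation-basis matches
# require approved/antineoplastic.

library(melresist)

norm <- median_of_ratios_normalize(
  filter_low_counts(read_counts_tsv("results/cohort/counts.tsv")))
maf <- read_maf("results/cohort_multi_sample.maf")
groups <- read.csv("results/sil_groups.csv")

interactions <- read_drug_interactions()
expressed <- expressed_gene_sets(norm)
mutated <- split(maf$Hugo_Symbol, maf$Tumor_Sample_Barcode)

# mutated samples are the 12-patient MAF cohort; expression sets come from
# the RNA cohort -- profiles are built per RNA sample with cohort-level
# mutation genes attached where no per-sample MAF exists
profiles <- lapply(groups$sample, function(s) {
  match_druggable_targets(
    s, expressed[[s]],
    if (!is.null(mutated[[s]])) mutated[[s]] else unique(maf$Hugo_Symbol),
    interactions,
    required_tags_mutation = c("approved", "antineoplastic"))
})

summary_tab <- summarize_drug_matches(
  profiles, setNames(groups$group, groups$sample))
write.table(summary_tab, "results/drug_matches.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("drug-target matches: %d (gene, drug, basis, group) rows",
                nrow(summary_tab)))
if (nrow(summary_tab)) {
  agg <- aggregate(weight ~ gene + basis, summary_tab, sum)
  for (i in order(-agg$weight)[seq_len(min(8, nrow(agg)))])
    message(sprintf("  %-8s (%s) matched in %d patient-group rows",
                    agg$gene[i], agg$basis[i], agg$weight[i]))
}
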