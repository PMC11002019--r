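#!/usr/bin/env Rscript
# Stage 2: low-count filtering, median-of-ratios normalization and
# resistant-vs-CR differential expression (PR samples excluded from the
# contrast, mirroring their heterogeneous outcome biology). Reports how much
# of the planted program the DE stage recovers.

library(melresist)

expr <- read_counts_tsv("results/cohort/counts.tsv")
truth <- jsonlite::read_json("results/cohort/truth.json",
                             simplifyVector = TRUE)

filtered <- filter_low_counts(expr)
message(sprintf("low-count filter: %d of %d genes retained",
                nrow(counts(filtered)), nrow(counts(expr))))

norm <- median_of_ratios_normalize(filtered)
message(sprintf("size factors: %.2f - %.2f", min(norm$size_factors),
                max(norm$size_factors)))

cls <- unlist(truth$class_labels)
de <- differential_expression(norm, names(cls)[cls == "PD"],
                              names(cls)[cls == "CR"])
write.table(de, "results/de_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

planted <- c(truth$up_genes, truth$down_genes)
hits <- de$gene[de$padj < 0.05]
message(sprintf(
  "DE at BH padj < 0.05: %d genes; planted-program recovery %.0f%%, false positives among nulls %.2f%%",
  length(hits), 100 * sum(planted %in% hits) / length(planted),
  100 * mean(de$padj[!de$gene %in% planted] < 0.05)))
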