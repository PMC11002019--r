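#!/usr/bin/env Rscript
# Stage 5: quantify phenotype densities per tissue region (cells/mm^2) and
# the CD8:Treg balance, comparing the peritumoral rim with the tumor core.

library(melresist)

cells <- read_cell_table_csv("results/cohort/cells.csv")
message(sprintf("%d cells (%d excluded by region QC)", nrow(cells),
                attr(cells, "qc_excluded")))

queries <- default_phenotype_queries()
dens <- density_table(cells, queries)
write.table(dens, "results/densities.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (ph in unique(dens$phenotype)) {
  sub <- dens[dens$phenotype == ph, ]
  message(sprintf("  %-10s intratumor %7.1f /mm^2   peritumor %7.1f /mm^2",
                  ph, sub$density[sub$region == "intratumor"],
                  sub$density[sub$region == "peritumor"]))
}

for (rg in c("intratumor", "peritumor", "total")) {
  r <- phenotype_ratio(cells, queries$cd8_t, queries$treg, rg)
  message(sprintf("CD8:Treg ratio (%s): %s", rg,
                  if (r$undefined) "undefined" else sprintf("%.2f", r$ratio)))
}

treg_ratio <- dens$density[dens$phenotype == "treg" &
                             dens$region == "peritumor"] /
  dens$density[dens$phenotype == "treg" & dens$region == "intratumor"]
message(sprintf("peritumor/intratumor Treg density ratio: %.2f", treg_ratio))
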