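#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Conditions: 24 samples per outcome class (PD-like resistant, CR-like
# responder, PR intermediate), 2,000 genes with 100 planted program genes at
# |log2FC| = 1.5, NB dispersion 0.1; mIF cell point patterns over a 2 mm^2
# tumor core and 1 mm^2 peritumoral rim; 40 annotated variant records; and
# exponential survival with class hazards 0.20/0.10/0.04 per month.

library(melresist)

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)
sim <- simulation_config(seed = 7)

cohort <- generate_expression_cohort(sim)
write_counts_tsv(cohort$matrix, "results/cohort/counts.tsv")
write_truth_json(cohort$truth, "results/cohort/truth.json")

cells <- generate_cell_table(sim)
write_cell_table_csv(cells, "results/cohort/cells.csv")

variants <- generate_variant_records(40, seed = 10)
write_variant_tsv(variants, "results/cohort/variants.tsv")

outcomes <- generate_outcomes(cohort$truth, sim)
write.csv(outcomes, "results/cohort/outcomes.csv", row.names = FALSE,
          quote = FALSE)

message(sprintf("cohort: %d genes x %d samples; %d planted program genes",
                nrow(counts(cohort$matrix)), ncol(counts(cohort$matrix)),
                length(c(cohort$truth$up_genes, cohort$truth$down_genes))))
message(sprintf("cells: %d segmented cells over %s regions",
                nrow(cells),
                paste(names(sim$region_areas), collapse = "/")))
message(sprintf("variants: %d records; outcomes: %d patients",
                nrow(variants), nrow(outcomes)))
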