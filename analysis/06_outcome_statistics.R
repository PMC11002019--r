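#!/usr/bin/env Rscript
# Stage 6: outcome statistics. Reproduces the published contingency-table
# tests from their printed counts, then runs the cohort-level comparisons on
# the synthetic cohort: Mann-Whitney on signature scores, Kaplan-Meier /
# log-rank on progression-free survival, and the score's ROC AUC.

library(melresist)

## published contingency tables, recomputed from printed counts
tabs <- list(
  gender_aya_vs_adult = matrix(c(29, 18, 47, 24), 2, byrow = TRUE),
  braf_subtype = matrix(c(36, 11, 24, 35), 2, byrow = TRUE),
  response_advanced = matrix(c(8, 13, 45, 26), 2, byrow = TRUE),
  adult_combo_vs_mono = matrix(c(25, 12, 20, 14), 2, byrow = TRUE),
  advanced_braf = matrix(c(8, 35, 13, 24), 2, byrow = TRUE),
  advanced_ldh = matrix(c(13, 47, 7, 24), 2, byrow = TRUE),
  advanced_stage = matrix(c(8, 33, 13, 38), 2, byrow = TRUE))
pub <- data.frame(
  comparison = names(tabs),
  fisher_p = vapply(tabs, function(t)
    suppressWarnings(as.numeric(fisher_exact(t))), numeric(1)))
treat <- matrix(c(7, 34, 5, 0, 9, 37), 3, byrow = TRUE)
pub <- rbind(pub, data.frame(comparison = "treatment_3x2_chisq",
                             fisher_p = chisq_contingency(treat)$p_value),
             data.frame(comparison = "treatment_3x2_freeman_halton",
                        fisher_p = as.numeric(freeman_halton(treat))))
write.table(pub, "results/published_contingency_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("published contingency tests:")
for (i in seq_len(nrow(pub)))
  message(sprintf("  %-30s P = %.4g", pub$comparison[i], pub$fisher_p[i]))

## synthetic-cohort outcome comparisons
outcomes <- read.csv("results/cohort/outcomes.csv")
scores <- read.delim("results/yim_scores.tsv")
lab <- setNames(outcomes$response, outcomes$sample)[scores$sample]

mw <- mann_whitney_u(scores$score[lab == "PD"], scores$score[lab == "CR"])
message(sprintf("Mann-Whitney YIM score PD vs CR: U = %.0f, P = %.3g (%s)",
                mw$U, mw$p_value, mw$method))

keep <- lab %in% c("PD", "CR")
message(sprintf("YIM ROC AUC (PD vs CR): %.3f",
                roc_auc(scores$score[keep], lab[keep] == "PD")))

surv <- survival_compare(
  data.frame(time = outcomes$pfs_months, event = outcomes$pfs_event,
             group = outcomes$response)[outcomes$response != "PR", ],
  "PD", "CR")
message(sprintf(
  "PFS: median PD %.1f vs CR %.1f months; log-rank chi2 = %.1f, P = %.3g",
  surv$medians[["PD"]], surv$medians[["CR"]], surv$chisq, surv$p_value))

kw <- kruskal_wallis(split(scores$score, lab))
message(sprintf("Kruskal-Wallis score across PD/PR/CR: H = %.1f, P = %.3g",
                kw$H, kw$p_value))

stats_out <- data.frame(
  test = c("mann_whitney_yim", "logrank_pfs", "kruskal_wallis_scores"),
  statistic = c(mw$U, surv$chisq, kw$H),
  p_value = c(mw$p_value, surv$p_value, kw$p_value))
write.table(stats_out, "results/outcome_statistics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
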