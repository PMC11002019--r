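# melresist

Immunogenomic analysis of immune checkpoint inhibitor (ICI) resistance in
adolescent and young adult (AYA) melanoma, packaged as a tested, reusable R
pipeline. It is written for computational oncologists who want to apply —
or audit — the analysis stack behind rank-based resistance signatures:

* **Directed rank-based single-sample scoring** (YIM/IPRES/IMMU-style
  signatures). For sample *i* against a signed gene set, all *G* measured
  genes are ranked once (ties averaged) and each observed set gene
  contributes its directed rank — the increasing-abundance rank for
  expected-up (+1) genes, `G + 1 − r` for expected-down (−1) genes:

  `S(dir, i) = Σ_g R(g, dir, i) / N(dir, i)`

  with `N(dir, i)` the number of set genes observed in the data. Scores are
  invariant under any monotone transform of a sample's expression.
* **Signature construction** from a negative-binomial Wald differential
  expression contrast of resistant (PD) vs complete-responder (CR) samples
  (PR excluded), signed by fold-change direction at BH-adjusted p < 0.05.
* **Immunophenogram profiles**: mean cross-sample z-scores of marker genes
  per immune category (effector cells, suppressor cells, checkpoints, MHC).
* **Somatic-variant filter cascade** (8 rules over duplex/UMI caller
  metrics, with TERT-promoter waivers and caller-specific rules) and MAF
  emission, plus sample-level mutation co-occurrence.
* **Spatial quantification** of mIF segmented-cell tables: phenotype
  densities (cells/mm²) per tumor-core / peritumoral region and derived
  ratios (e.g. CD8:Treg).
* **Outcome statistics**: exact Fisher 2×2 and Freeman–Halton r×c tests by
  enumeration, Mann–Whitney U (exact/normal), Kruskal–Wallis, Spearman,
  Kaplan–Meier + Mantel–Cox log-rank, ROC AUC, BH and two-stage BKY
  adjustments.
* **Druggable-target matching** of expressed/mutated genes against a
  drug–gene interaction table with category-tag filters.
* A **synthetic cohort generator** (NB counts with a planted resistance
  program, Poisson cell point patterns, designed variant records,
  exponential survival) so the whole pipeline runs without external data.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_signature_scores.R
# ... through 07_drug_targets.R
```

Stage 2 and 3 print, for the default conditions (24 samples per class,
2,000 genes, 100 planted program genes at |log2FC| = 1.5, seed 7):

```
low-count filter: 1977 of 2000 genes retained
size factors: 0.56 - 1.78
DE at BH padj < 0.05: 106 genes; planted-program recovery 98%, false positives among nulls 0.43%
YIM signature: 106 genes (54 up in PD, 52 up in CR)
PD-vs-CR AUC 1.000; beats 100/100 random same-size signatures
```

That is: the DE stage finds 106 significant genes of which 98 are planted
program genes (98% recovery, 0.43% of null genes falsely called), and the
signature rebuilt from them separates resistant from responding samples
perfectly — and better than every one of 100 random signatures of the same
size. Stage 5 prints region densities (e.g. Tregs at 74.5/mm² in the tumor
core vs 203.0/mm² in the peritumoral rim — the stroma-infiltrating pattern
the generator plants), and stage 6 reproduces the published
contingency-table tests from their printed counts and runs the survival and
rank comparisons on the synthetic cohort.

The same workflow is available programmatically:

```r
library(melresist)
cfg <- pipeline_config(out_dir = "results/run", seed = 7)
run_pipeline(cfg)   # writes all stage outputs plus manifest.json
```

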