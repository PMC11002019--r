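---
title: "Methods: rank-based resistance signatures and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based resistance signatures and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melresist)
```

# What this package computes

`melresist` re-implements, as a tested pipeline, an immunogenomic analysis
of immune checkpoint inhibitor (ICI) resistance in adolescent and young
adult (AYA) melanoma: a directed rank-based single-sample signature of
baseline immunosuppression (the YIM-style score), the differential-expression
stage that constructs it, immunophenogram category profiling, a somatic
variant filter cascade with MAF emission, peritumor/intratumor cell-density
quantification from multiplex immunofluorescence (mIF) segmentations, the
outcome statistics used throughout (exact contingency tests, rank tests,
survival comparison, ROC evaluation), and druggable-target matching.
Because the patient-level data live in controlled-access archives, the
package ships a synthetic cohort generator that reproduces the statistical
structure each stage assumes, so everything is exercised end to end in code.

# The directed rank score

A directed gene set carries a sign per gene: +1 for genes expected up in
ICI-resistant disease, -1 for genes expected up in complete responders.
For sample $i$ with $G$ measured genes, all genes are ranked once by
abundance (ties averaged). Each observed set gene $g$ contributes its
directed rank $R^g_{dir,i}$: the increasing-abundance rank for +1 genes and
the decreasing rank $G + 1 - r$ for -1 genes. The score is the mean

$$S_{dir,i} = \frac{\sum_g R^g_{dir,i}}{N_{dir,i}},$$

where $N_{dir,i}$ counts the set genes actually observed in the data —
absent genes are excluded from both numerator and denominator. The score is
therefore invariant under any strictly increasing transform of a sample's
expression values (and under library-size scaling, which is a special
case), lies in $[1, G]$, equals $(G+1)/2$ for the all-genes +1 set, and
maps to $G + 1 - s$ under full sign reversal in tie-free data.

Two design points were genuinely open:

* **Normalization.** The defining formula is a raw mean rank, without the
  min–max rescaling some single-sample scoring tools apply. We report the
  raw mean rank as the primary score and expose `normalize = TRUE`
  (`(s - 1)/(G - 1)`) as an option; the rescaling is monotone, so AUCs and
  rank-based comparisons are unaffected.
* **Pooling.** Up- and down-weighted genes are pooled into a single mean of
  directed ranks, matching the single sum of the formula. A two-block
  variant (`method = "two_block"`, the sum of the separate up-block and
  down-block means) is available for sensitivity analysis.

Ties take fractional (average) ranks — the standard, deterministic choice
for rank statistics.

Signature construction takes the differential-expression table of the
resistant (PD) versus complete-responder (CR) contrast — with partial
responders excluded upstream, reflecting their heterogeneous biology and
outcomes — and signs genes at adjusted $p < 0.05$ by their fold-change
direction. IPRES-style comparator sets are scored with all weights +1; the
IMMU-style composite pools effector components (chemokine, interferon-γ,
T effector, T-cell inflamed) with weight +1 and suppressive components
(β-catenin, TGF-β, immunosuppression) with weight -1. The packaged
component lists are synthetic placeholders (the canonical lists are not in
the public methods text) and are replaceable by any signed or plain GMT
file.

# Differential expression

The DE stage is a deliberate approximation of the standard negative
binomial Wald workflow, documented as such:

* genes are dropped unless their count exceeds 20 in more than 5 samples —
  the published filter sentence is ambiguous about strictness and scope, and
  this reading (keep iff $\#\{j: k_{gj} > 20\} > 5$) removes exactly the
  low-information genes the filter targets; both bounds are arguments;
* size factors are median-of-ratios over the genes expressed in every
  sample (the same estimator as the reference implementation, which the
  test suite cross-checks against DESeq2 on a small matrix);
* per-gene dispersion is a pooled within-group method-of-moments estimate
  $\hat\alpha = (s^2 - \bar y)/\bar y^2$ on normalized counts, floored at
  $10^{-8}$; there is no shrinkage, no independent filtering and no
  covariates;
* the Wald statistic is the difference of log normalized group means over a
  delta-method standard error $\sqrt{\sum_k (\bar y_k + \hat\alpha \bar
  y_k^2)/(n_k \bar y_k^2)}$, referred to the standard normal, with a
  pseudo-count of 0.5 on means for the reported log2 fold change;
* BH adjustment across tested genes.

Under the global null this yields approximately uniform p-values
(Kolmogorov–Smirnov distance below 0.05 at 2,000 genes in the seeded test),
and on the planted cohort it recovers the program with high power (below).
Accepting this approximation means p-values are not numerically identical
to any particular DESeq2 release; all downstream guarantees are therefore
stated as recovery and discrimination properties, not as p-value equality.

The BKY (two-stage step-up) adjustment reports values at a fixed
$\alpha = 0.05$: stage 1 runs BH at $\alpha/(1+\alpha)$ to estimate the
null count $m_0 = m - r_1$, and the reported value for the $i$-th ordered p
is the step-up monotonization of $p_{(i)}(1+\alpha)m_0/i$, so that
"adjusted $\le \alpha$" reproduces the two-stage rejection set exactly (the
test suite checks this equivalence). Because of the $(1+\alpha)m_0/m$
factor this adjusted value is a *fixed-level report*, not a level-free
q-value: a single p-value is returned slightly inflated unless it is 1.

# The variant filter cascade

Variants arrive as a flat table of caller metrics (a minimal VCF reader
with a configurable INFO-key map is provided; the annotation schema of the
upstream commercial pipeline is proprietary). A record is kept iff it
passes every applicable rule:

1. unique depth UDP > 10, and unique alt observations UAO > 6 and duplex
   alt observations DAO > 1 — the UAO/DAO parts waived for TERT-promoter
   records;
2. homopolymer count < 6;
3. gnomAD AD < 0.01 and global AF < 0.01;
4. no positive call for sequencing direction bias or sample strand bias
   (both boolean flags false);
5. sequence direction strand bias probability > 0.1 (waived for TERT
   promoter);
6. FreeBayes calls only: (sample strand bias probability > 0.05 or ratio
   > 0.4) and 95MDAF < 0.2;
7. LoFreq calls only: 0.1 < AF ≤ 0.2, implemented exactly as printed (the
   upper bound may be an upstream typo; both bounds are configurable);
8. coding variants kept only with HIGH/MODERATE impact; non-coding only
   with a 5' UTR or upstream-gene consequence.

The keep decision is conjunctive, hence independent of rule order; only the
*attribution* of a dropped record (to its first failing rule, in the
printed order) depends on it. TERT-promoter membership is an input flag or
derived from a user-supplied genomic interval — no coordinates are
hard-coded, since they are assembly-dependent. Upstream sequencing-QC
sample exclusion (average-unique-DNA score below 50) concerns raw run
metrics that are not part of these inputs and is a documented manual step.
Kept records are emitted as standard MAF rows (1-based inclusive
coordinates); missing gene symbols become "Unknown" with a warning.

# Spatial quantification

Cell tables are HALO-style exports: coordinates in μm, a region label
(tumor core vs peritumoral stroma; the upstream random-forest tissue
classifier is out of scope), and binarized marker flags (positivity
thresholding also happens upstream). Phenotypes are marker queries with
required-positive and required-negative sets (T cell: CD3⁺SOX10⁻; Treg:
CD3⁺FOXP3⁺SOX10⁻; and so on). Density is count over the declared region
area in mm²; ratios with a zero denominator are flagged undefined rather
than thrown; cells with undeclared region labels (necrosis, folds,
artifacts) are excluded and counted in a QC attribute. The conservation
identity — density × area summed over regions equals the total matching
count — is property-tested on random tables.

# Outcome statistics

The exact tests are implemented in the package because their conventions
matter for reproducing printed values:

* **Fisher 2×2**: two-sided by probability ordering — the sum of
  hypergeometric probabilities of all margin-consistent tables no more
  probable than the observed one, with a relative tolerance of $10^{-7}$ on
  probability comparisons so enumeration is robust to floating-point ties.
* **Freeman–Halton r×c**: full depth-first enumeration over
  margin-consistent tables (cohort totals here are ≤ 118, enumeration takes
  milliseconds); a seeded Monte-Carlo fallback (Patefield sampling) guards
  against combinatorial blow-up and records its method in the result.
* **Pearson chi-square** (no continuity correction) is provided alongside,
  because the published multi-row comparisons used the chi-square route:
  on the 3×2 treatment table the chi-square P (0.00013) reproduces the
  printed 0.0001, while the exact enumeration gives 0.00082.
* **Mann–Whitney U** uses exact enumeration of the permutation
  distribution up to 8 per group and the tie-corrected normal approximation
  (no continuity correction) beyond.
* **Kruskal–Wallis** delegates to `stats::kruskal.test` with an explicit
  all-ties convention (H = 0, P = 1); **Spearman** is the Pearson
  correlation of average ranks with the t approximation; **ROC AUC** is the
  rank-sum (concordance) formula, identical to the trapezoidal area and
  tied to U by AUC = U/(n₁n₂), which is property-tested.
* **Survival**: Kaplan–Meier curves and the Mantel–Cox log-rank test
  delegate to the `survival` package; the group median is the first time
  with $S(t) \le 0.5$ (no interpolation, NA when never reached), computed
  directly from the fitted curve so the convention is explicit.

A two-way ANOVA is mentioned in the source methods but no in-scope result
depends on it; it is omitted.

# The synthetic cohort generator

The generator defines the study conditions; its defaults are fixed once:

* **Expression**: three outcome classes (resistant PD-like, CR-like, PR)
  of 24 samples each; 2,000 genes; negative binomial counts parameterized
  by mean and dispersion (variance $\mu + \alpha\mu^2$) with a shared
  $\alpha = 0.1$ — typical of bulk RNA-seq; the DE stage estimates
  dispersion per gene and does not assume sharing. Per-gene baselines are
  log-normal around a mean count of 100 (sdlog 1) and per-sample
  library-size factors are log-normal (sdlog 0.2), so normalization has
  something to do. The published cohort's dispersion and library spread
  are not reported; these values are the package's own choice of a
  realistic regime. A planted program of 100 genes (half up, half down)
  is shifted by $2^{\pm 1.5}$ in the PD class; PR samples get half the
  effect, to exercise the rule of excluding PR from signature training.
* **Cells**: homogeneous Poisson counts per (phenotype, region) with
  intensities in cells/mm² over two disjoint square regions (tumor core
  2 mm², peritumoral rim 1 mm²; coordinates in μm). Default intensities
  put tumor cells at 2000/100 (core/rim), T cells at 200/400, CD8 T cells
  at 150/250 and Tregs at 50+20/150+60 — i.e. peritumoral lymphocyte
  enrichment, the stroma-infiltrating pattern of resistant tumors.
* **Variants**: a designed block of 20 records covers the pass and fail
  branch of every filter rule, both callers and the TERT-promoter waivers;
  records beyond 20 are seeded random perturbations.
* **Outcomes**: exponential progression-free survival with hazards
  0.20/0.10/0.04 events per month for PD/PR/CR (overall survival at half
  those hazards), independent exponential censoring at rate 0.02, and
  treatment assignment skewed toward combination ICI among responders.

Determinism is strict: the same seed gives bit-identical outputs, and the
pipeline expands its global seed into fixed per-stage offsets so adding a
stage never perturbs earlier stages' randomness.

What the generator does **not** emulate: batch effects, gene–gene
correlation, read-level sequencing artifacts, image pixels, segmentation
error, or non-exponential survival. Passing tests therefore demonstrate
that the implementations compute their definitions correctly and recover
planted structure under the stated model — not that the biological
conclusions transfer to any real cohort.

# Problem sizes and seeds used by the checks

The standard conditions for the recovery checks are 24 samples per class,
2,000 genes, 100 planted genes at $|log2FC| = 1.5$ — at these sizes the DE
stage recovers ≥ 90% of the program with ≲ 1% false positives and the
rebuilt signature separates PD from CR with AUC ≈ 1, beating essentially
all random same-size signatures. Scoring-oracle checks run 200 random
instances of up to 50 genes against a brute-force pairwise-counting rank
oracle; exact-test oracles enumerate tables with totals ≤ 30; survival
recovery uses 500 uncensored exponential draws, where the KM median has a
sampling error of a few percent around $\ln 2 / h$. The null-uniformity
checks use 200–500 seeded replicates.

# Known limitations

* The DE stage is a moment/Wald approximation; borderline genes can differ
  from shrinkage-based implementations, and guarantees are stated as
  recovery properties.
* The BKY adjusted values are fixed-level reports (see above).
* The Freeman–Halton enumeration is exponential in principle; the
  Monte-Carlo fallback is accurate to its sampling error and flags itself.
* The immunophenogram grouping threshold (SIL-high vs SIL-low) is a
  reconstruction — the qualitative stratification rule is not printed in
  the source methods — and is exposed as an explicit parameter.
* Packaged marker lists, comparator signatures and the drug–gene
  interaction snapshot are editable placeholders, not authoritative
  releases; the drug matcher's "expressed" threshold (cohort upper
  quartile per gene) is likewise configurable, as no threshold is printed.

# Worked example

```{r example, eval = FALSE}
sim <- simulation_config(seed = 7)
cohort <- generate_expression_cohort(sim)
norm <- median_of_ratios_normalize(filter_low_counts(cohort$matrix))
cls <- cohort$truth$class_labels
de <- differential_expression(norm, names(cls)[cls == "PD"],
                              names(cls)[cls == "CR"])
yim <- build_directed_signature(de)
scores <- score_cohort(norm, yim)
lab <- cls[scores$sample]
roc_auc(scores$score[lab != "PR"], lab[lab != "PR"] == "PD")
```

The numbered scripts under `analysis/` run this workflow end to end and
write their tables under `results/`.
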