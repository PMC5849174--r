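---
title: "Methods: case-control PRS construction and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control PRS construction and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Candidate-SNP studies of complex disease genotype a few dozen
literature-selected variants in a case-control sample and ask two questions:
which SNPs are associated with disease in this population, and how well does
a polygenic risk score (PRS) built from them stratify risk? The design that
`prspipe` implements uses two independent cohorts: a training cohort
estimates per-SNP odds ratios, and a held-out evaluation cohort is scored
and stratified, so the discrimination estimates are not inflated by
winner's curse on the weights.

## Quality control

Three filters run before any association testing, each logged per SNP with
explicit reasons:

* **Call rate.** Samples and SNP assays need at least 95% non-missing calls.
  Comparisons are `>=`, so a sample at exactly 95% passes.
* **Hardy–Weinberg equilibrium (HWE), in controls only.** Departures from
  the p², 2pq, q² genotype proportions among controls signal genotyping
  artifacts; cases are excluded because true risk loci can deviate in cases.
  The default test is the exact conditional test — given the minor-allele
  count, the heterozygote count has a known discrete distribution, and the
  two-sided p sums all configurations no more probable than the observed one
  (implemented by the ratio recurrence; the test suite checks it against an
  independent closed-form enumeration for every configuration up to 50
  diploids). The exact test matters here because candidate panels include
  rare variants for which the 1-df chi-square approximation is poor; the
  chi-square version is kept for cross-checking. There is no universal
  exclusion threshold, so it is an explicit parameter (default p < 1e-6).
* **Minor allele frequency (MAF).** SNPs with MAF below 1% are removed. We
  read "present in less than 1%" as *allele* frequency (not carrier
  frequency), computed from non-missing calls of the cohort under analysis,
  cases and controls combined. Rare risk variants — the ones this filter
  removes — are precisely those whose odds ratios cannot be estimated
  stably at candidate-study sample sizes.

## Per-SNP association

Each SNP is tested alone by logistic regression of case status on the
effect-allele dosage (0/1/2; the additive model), optionally with age as a
linear covariate on the logit scale. Missing genotypes are excluded pairwise
per SNP (matching the per-assay call-rate framing) rather than listwise
across the panel. Estimation is maximum likelihood via IRLS (deviance
tolerance 1e-10, 100 iterations) with Wald standard errors from the inverse
observed information; `exp(beta ∓ 1.96·se)` gives the 95% CI. Complete or
quasi-complete separation is detected from boundary fitted probabilities and
flagged as non-converged — such SNPs never contribute weights to a score.
Significance means p ≤ 0.05, deliberately without multiple-testing
correction, because the downstream model-selection rules are defined on the
uncorrected scale; a Bonferroni column is emitted for transparency only.

## LD pruning

Pairwise linkage disequilibrium is the *composite* r²: the squared Pearson
correlation between dosage vectors over pairwise-complete samples. It is
phase-free and deterministic, and equals haplotype r² exactly when phase is
unambiguous; an EM haplotype estimator is out of scope. Pairs at r² ≥ 0.5
count as moderate-to-strong LD. A *block* is a connected component of the
graph with those edges — the unambiguous closure of "in LD with each other",
chosen over clique-based definitions because it never depends on vertex
order. Pruning keeps exactly one SNP per block: smallest association p,
ties broken by larger |log OR|, then by genomic position. The tie-break
chain is our own convention (with continuous data ties are measure-zero);
it exists so results are reproducible bit-for-bit.

## The score and the three models

The PRS of individual *i* is

PRS_i = Σ_j ŵ_j · g_ij,

with ŵ_j the **natural-log** odds ratio of SNP *j* estimated in the
training cohort (natural log keeps the weights on the same scale as the
logistic-regression coefficients) and g_ij the effect-allele count. Three
selection rules, each available with unadjusted or age-adjusted weights:

* **model1** — every QC-passing SNP;
* **model2** — only SNPs significant at α = 0.05 in the chosen analysis;
* **model3** — model2 after LD pruning.

The rules nest (model3 ⊆ model2 ⊆ model1). Missing genotypes at scoring
time are imputed by default with twice the effect-allele frequency among
*training* controls, which keeps the score scale comparable across samples;
a per-sample renormalization (sum of observed terms scaled by m/m_observed)
is available as an alternative. Training/evaluation separation is a
contract: the pipeline refuses to score the cohort the weights came from
unless an explicit override is set.

## Evaluation

* **Quartiles.** Cutpoints are the 25th/50th/75th percentiles of the
  *control* score distribution (configurable to the combined cohort). The
  control anchor is the convention that splits the evaluation controls into
  near-equal quarters regardless of case load. Percentiles use quantile
  type 6 — the definition used by SPSS-family software and the one that
  splits 243 controls 61/61/61/60 — and samples exactly at a cutpoint go to
  the lower quartile. Per-quartile odds ratios against the first quartile
  come from a one-hot logistic fit; because that model is saturated, each
  OR equals the crude cross-product ratio of the corresponding 2×2 counts,
  which is why published quartile tables are exactly recomputable from
  their printed counts (`quartile_or_from_counts()`). Identical scores for
  all samples make the cutpoints degenerate, which is an error; a quartile
  with zero cases or controls yields an undefined OR, flagged, not fudged.
  Note that when a model contains very few SNPs the score is coarsely
  discrete, ties at cutpoints become real, and the control split can
  legitimately deviate from 61/61/61/60.
* **Trend.** Logistic regression of status on the PRS as a continuous
  variable (plus age if requested); the reported OR is per unit of PRS and
  therefore not comparable across models with different weight scales —
  smaller models concentrated on stronger SNPs typically show larger
  per-unit trend ORs.
* **AUC.** The Mann–Whitney estimator (probability a random case outscores
  a random control, ties counted 1/2) with a DeLong 95% CI, via `pROC`. The
  test suite pins the estimator to exhaustive pair enumeration.

## The simulator

`simulate_study()` generates the two cohorts the analysis assumes, plus
truth metadata for parameter-recovery tests.

* **Genotypes.** Unblocked SNPs are independent binomial(2, EAF) draws. LD
  blocks use a latent-Gaussian threshold copula on haplotypes: within a
  block each haplotype's latent variables share one factor, and the factor
  loading is calibrated (by 1-d quadrature of the bivariate normal and root
  finding) so the mean pairwise *allele* correlation equals √r². Because an
  individual's dosage is the sum of two independent haplotypes, the dosage
  correlation equals the allele correlation, so realized dosage r² targets
  the configured block r² (the suite asserts within ±0.05 bands at
  n = 2000). Frequency pairs whose maximum attainable correlation is below
  the target raise a calibration error.
* **Disease.** Case probability is logistic(α + Σ log(OR_j)·g_ij), with α
  tuned by bisection to a baseline prevalence of 10%. Cohorts are filled by
  oversampling the population until the case and control quotas are met;
  odds ratios are invariant to this outcome-dependent sampling, so the
  prevalence only sets the rejection-sampling efficiency. Cohort sizes
  describe samples *after* sample-level QC, so quota filling skips the
  occasional sample below the 95% call-rate threshold — with the default
  0.5% missingness this keeps the evaluation cohort at exactly its nominal
  301/243 and hence the 61/61/61/60 control quartile split.
* **Age.** With a zero age–risk slope (default), ages are drawn per class
  from truncated normals on [20, 90] (defaults: cases 50.2 ± 9, controls
  42.7 ± 9 in cohort 1; 49.9/42.0 in cohort 2) — age is then associated
  with status but not with genotype, so adjusted and unadjusted ORs agree
  in expectation. With a non-zero slope, age is drawn first and enters the
  disease model, letting tests construct genuine age confounding.
* **The preset panel** (`default_snp_panel()`) has 51 SNPs: 5 rare variants
  with large effects (ORs 2.6–4.9) whose population EAFs (0.08–0.15%) are
  set low enough that even after case enrichment — the case-allele
  frequency of a rare variant scales roughly with its OR, and the cohort is
  case-heavy — the realized cohort MAF stays below the 1% filter, making
  the 51 → 46 QC attrition deterministic in practice; one 4-SNP block at
  r² ≈ 0.85 in which a single causal SNP (OR 1.4) is tagged by three
  neutral SNPs (one causal variant per block, the parsimonious choice);
  7 independent causal SNPs (ORs 1.15–1.30); and 35 nulls. At the default
  cohort sizes this yields around 10–12 significant SNPs, a 4-SNP block
  pruned to its strongest member, and evaluation AUCs near 0.58.

What the simulator does **not** emulate: population structure and admixture,
relatedness, genome-scale LD maps, genotyping batch effects, X-chromosome
dosage, and phenotype misclassification. Passing tests therefore demonstrate
correctness of the estimators and the pipeline contract under clean
sampling assumptions, not robustness to those real-data complications.

## Problem sizes and tolerances in the test suite

Chosen so Monte-Carlo error is small relative to each assertion band:
Wald-CI coverage of a true OR 1.4 (EAF 0.3) uses 500 replicate cohorts of
2000 + 2000 with a 93–97% acceptance band; the type-I error of the per-SNP
test under the null uses 4000 replicates against a 4–6% band (at 500
replicates the Monte-Carlo standard error would be as large as the band);
these replicates set the simulator's prevalence to 50%, which only improves
rejection-sampling efficiency. The end-to-end null check (all ORs 1) uses
two cohorts of 5000 + 5000: every non-reference quartile CI must cover 1
and the AUC must fall within 0.5 ± 0.02. The exact-HWE sweep is exhaustive
for all genotype configurations up to 50 diploids. Realized-frequency
checks run at n = 20,000 where the ±0.01 band is >4 Monte-Carlo standard
deviations.

## Known limitations

* Weights are plug-in log ORs from single-SNP fits; no shrinkage, no joint
  model, no external-weight meta-analysis (an `external_weight` slot exists
  in the manifest for user-supplied weights).
* The composite r² underestimates haplotype r² when departures from HWE are
  present; acceptable here because QC enforces HWE in controls.
* Quartile ORs are crude (unadjusted) by construction of the saturated
  model; covariate-adjusted stratified ORs would need a different estimand.
* The AUC of a candidate-panel PRS is expected to be modest (≈0.55–0.60);
  the package reports discrimination, it does not calibrate absolute risk.
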