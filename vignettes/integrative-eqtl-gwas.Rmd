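---
title: "Integrative cis-eQTL and GWAS analysis with cisMetaQTL"
author: "cisMetaQTL authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative cis-eQTL and GWAS analysis with cisMetaQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisMetaQTL)
```

# Overview

`cisMetaQTL` links noncoding disease-risk variants to their putative
target genes by combining two lines of evidence in the same variants:
a case-control GWAS meta-analysis, and a cis-eQTL meta-analysis in
disease-relevant tissue. A variant is promoted to a candidate
variant–gene pair when it is a suggestive GWAS signal (pooled
$P < 10^{-5}$, nominal $p < 0.05$ in every cohort, concordant
direction) *and* a significant eQTL (meta-analysis FDR < 0.05) for some
gene within 1 Mb of its transcription start site.

Because real genotype–expression cohorts of this kind are controlled
access, the package carries a first-class synthetic-cohort generator
with full ground truth. Every statistical property claimed for the
pipeline — false-discovery calibration, effect recovery, the power gain
of pooling, heterogeneity triage rates, enrichment calibration — is
demonstrated on data from that generator in the test suite.

# The association models

## cis-eQTL mapping

For gene $g$ with inverse-normal transformed expression $y_g$ and
variant $v$ with allele dosage $x_v \in [0,2]$, the per-cohort model is

$$ y_g = \alpha + \beta\, x_v + C\gamma + \varepsilon, $$

with $C$ the covariate matrix (measured covariates, ancestry PCs,
hidden expression factors). Pairs are enumerated for
$|\mathrm{pos}_v - \mathrm{TSS}_g| \le 10^6$ bp, inclusive at both
boundaries; for minus-strand genes the TSS is the annotated end
coordinate and the signed TSS distance is flipped so that positive
always means downstream of transcription.

`mapCohort()` fits all pairs through a residualization fast path: $y$
and $x$ are residualized on $[1, C]$ once, after which each pair is a
simple regression whose degrees of freedom are reduced by the covariate
count. By the Frisch–Waugh theorem this is numerically identical to the
full multiple regression; the test suite asserts agreement with direct
OLS to $10^{-8}$ on the $t$ statistic.

## Meta-analysis and heterogeneity

Per-study estimates $(\beta_i, se_i)$ are pooled with fixed-effects
inverse-variance weights $w_i = se_i^{-2}$:

$$ \hat\beta = \frac{\sum w_i \beta_i}{\sum w_i}, \qquad
   se(\hat\beta) = \Big(\sum w_i\Big)^{-1/2}, $$

with $p$ from the normal approximation of $z = \hat\beta/se$ (the
fixed-effects convention; not the $t$ distribution). Heterogeneity is
measured by Cochran's $Q = \sum w_i(\beta_i - \hat\beta)^2$ with
$P_{het}$ from $\chi^2_{k-1}$, and $I^2 = \max(0, (Q - df)/Q) \cdot
100$ (defined as 0 when $Q = 0$). The triage rule flags *substantial*
heterogeneity when $I^2 \ge 75\%$ and $P_{het} < 0.05$; flagged pairs
are retained but labelled, since attenuated effects in a tumor cohort
relative to normal tissue are expected rather than disqualifying.

Before pooling, summary tables carrying allele columns are harmonized:
a study whose effect/other alleles are swapped relative to the first
study has its $\beta$ sign flipped, and strand-ambiguous (A/T, C/G)
mismatches are dropped with a warning. Pairs observed in only one
cohort pass through as $k = 1$ rows labelled `single_cohort` (cohort
coverage genuinely differs between expression panels), unless
`requireAll` asks for complete cases.

Published stages reported only as an odds ratio with a 95% CI are
combined by `combineORStages()`: each stage is converted to the log
scale with $se = (\ln U - \ln L)/(2 \cdot 1.96)$ and pooled as above.
This is how a discovery and a replication stage are merged from their
printed summaries alone; the recomputed pooled $p$ is close to, but not
exactly, what unrounded inputs would give, so only the OR and bounds
should be compared at printed precision.

## Enrichment against matched non-eQTLs

Lead eQTLs (per gene: minimal FDR, ties broken by raw $p$, then
$|\beta|$, then variant id) are compared with an equal-size control set
drawn from non-significant pairs (FDR ≥ 0.05), matched on MAF and
|TSS distance|. Matching bins are MAF deciles of the pooled
lead-plus-pool distribution and log-decade distance edges at 0, 1 kb,
10 kb, 100 kb, 1 Mb. Draws are without replacement within the matching
cell; an exhausted cell borrows from the nearest cell by Manhattan
distance on bin indices (ties resolved toward the lower MAF bin), with
every borrow logged. One matched set is drawn per run; replicate-level
calibration lives in the test suite.

Overlap enrichment uses Fisher's exact test (two-sided,
minimum-likelihood rule). The odds ratio is the sample
$(ad)/(bc)$ with a Woolf log-scale CI; the Haldane–Anscombe 0.5 is
added to all cells only when a cell is zero, and only for the OR and CI
— never for the exact $p$. Families of annotations are adjusted by BH
(functional categories, histone marks) or Bonferroni (TF and RBP
panels). Gene-set over-representation for eGenes is the upper
hypergeometric tail.

## GWAS, inflation, and power

Per-cohort case-control association is additive-model logistic
regression (IRLS, deviance tolerance $10^{-12}$, 100 iterations max)
with Wald statistics; separation or non-convergence flags the variant
(`converged = FALSE`, $|\log OR| > 10$) and excludes it from selection.
Genomic inflation is $\lambda = \mathrm{median}(\chi^2_{obs}) / 0.4549$.
Suggestive variants are grouped into loci by greedy 500-kb clumping
around index variants processed in ascending $p$ — the grouping rule is
a declared convention, since published locus counts rarely state one.

Analytic power uses the Cochran–Armitage trend test (scores 0, 1, 2)
under an additive-on-risk penetrance model: with prevalence $K$,
risk-allele frequency $q$, and per-allele relative risk $R$, the
baseline penetrance solves
$f_0[(1-q)^2 + 2q(1-q)R + q^2(2R-1)] = K$, case and control genotype
distributions follow by Bayes' rule, and power is the upper tail of the
noncentral $\chi^2_1$ beyond the central critical value. The per-allele
"OR" quoted by genetic power calculators is interpreted as this
relative risk; prevalence defaults to 0.01 and is exposed as a
parameter, because quoted power values depend on it materially (at
MAF 0.20, RR 1.20, $\alpha = 10^{-5}$, 5130/5776 cases/controls the
analytic power is 0.833 at 1% prevalence; calculators assuming other
prevalences print values several points higher).

# The synthetic-cohort generator

`simulateStudy()` draws, from a single master seed (all per-operation
substreams are derived deterministically from it, so the variant panel
is shared across cohorts while samples are independent):

- **Genotypes**: two haplotypes per sample from a Gaussian copula with
  block-diagonal lag-one latent correlation (`ldBlockSize`, `ldRho`),
  thresholded at the allele-frequency quantile. Marginals are exactly
  Bernoulli(MAF) per haplotype, so genotypes are in Hardy–Weinberg
  proportions; within-block LD is tunable and oracle-checkable by
  direct large-sample simulation. Missing dosages are injected
  completely at random (`missingRate`, default 0).
- **Expression**: latent value = baseline + $\beta \cdot$ dosage for
  planted causal pairs (validated to lie inside the cis window) +
  hidden-factor term + optional known-covariate term + N(0, `noiseSd`)
  noise, mapped to a positive FPKM-like scale by exponentiation with a
  per-gene scale. A configurable fraction of genes (`lowExprFraction`)
  is forced below mean FPKM 0.1 to exercise the expression filter. The
  map is monotone per gene, so the inverse-normal transform recovers
  the latent ranks exactly.
- **Phenotypes**: case probability = inverse-logit of an intercept +
  planted per-allele log-ORs × dosage + modest age/sex effects; the
  intercept is solved by bisection (tolerance $10^{-6}$) so the
  sample-average probability equals `caseFraction`; statuses are
  independent Bernoulli draws.
- **Annotations**: an interval track covering causal variants with
  `enrichmentRatio` times the background coverage probability, plus a
  categorical label per variant with causal variants preferentially
  non-intergenic.

Ground truth (causal pairs with per-cohort $\beta$, risk variants with
log-OR, factor loadings) is returned as a `SimTruth` object and written
with the fixtures.

Default conditions mirror a two-cohort pancreatic-tissue design: cohort
sizes 177 and 305, cis effect 0.25 expression-SD per allele, risk OR
1.20, case fraction 0.47, MAF range 0.05–0.5, LD blocks of 10 at latent
correlation 0.5. Half of the risk variants coincide with causal eQTL
variants by default (`riskOverlapFraction = 0.5`): the premise of the
integrative design is that some risk alleles act through expression,
and without overlap the intersection would be empty by construction.

What the generator does *not* emulate: realistic recombination maps or
LD decay (LD is blockwise stationary), population structure beyond the
two-subpopulation fixtures used in the PCA tests, imputation
uncertainty (the quality score is a label, not a model), cell-type
composition, or count-level expression noise. Passing tests therefore
demonstrate the statistical machinery — calibration, recovery,
ranking — under the stated model, not robustness to every artifact of
real cohorts.

# Numerical choices and conventions

- **Inverse-normal transform**: $\Phi^{-1}((r - 0.5)/n)$ with average
  ranks for ties — the common eQTL-pipeline convention, symmetric, and
  exactly mean-zero without ties. Constant vectors map to all zeros
  with a warning. Note the transform standardizes total expression
  variance, so recovered slopes are mildly attenuated relative to the
  latent scale by $1/\mathrm{sd}(y_{latent})$; at the default effect
  sizes this is under 2%.
- **Hardy–Weinberg**: the exact conditional test (complete enumeration
  in log space, minimum-likelihood two-sided rule), because the filter
  operates at $P > 10^{-5}$ where chi-square asymptotics fail for rare
  variants. Dosages are rounded to hard genotypes for the counts.
- **QC order**: MAF, missingness, HWE, quality — fixed so the reported
  first-failing reason is deterministic; `variantQC` is idempotent.
- **Hidden factors**: the top singular vectors of the expression matrix
  after gene-wise residualization on known covariates, with the
  conventional count of 15. This is a deterministic surrogate for
  probabilistic expression-residual factor models: it captures the same
  dominant confounding directions without a variational fit, at the
  cost of no automatic relevance determination. The count is
  configurable and capped below the matrix rank.
- **Degenerate fits**: a perfect fit reports $p$ at the smallest
  positive representable double with a `perfect_fit` flag, never 0;
  zero-variance inputs yield flagged records with missing statistics.
- **BH pool**: global across all tested pairs in a run — pooled
  p-values are adjusted in one family, with no per-gene hierarchy.
- **Fisher two-sided p**: minimum-likelihood rule (sum of tables with
  probability ≤ observed), matching the standard exact-test convention.
- **Matched-draw testability**: exact-test p-values are discrete and
  conservative at small set sizes, so the calibration property
  (KS-uniformity of enrichment p-values under independent annotation)
  is demonstrated at 1000 leads against a pool of 10,000 — large enough
  that the null distribution is effectively continuous.

# Problem sizes used by the test suite

The acceptance-level properties run at sizes chosen to make Monte-Carlo
bounds tight while keeping the suite fast on a single core: 50 null
studies of 2 × 150 samples (≈ 4,000–5,000 cis pairs each) for FDR
calibration plus one ≈ 9,000-pair study for KS uniformity; 200 planted
pairs at $\beta = 0.25$, 2 × 300 samples for recovery and coverage; 100
replicates of 20 pairs at 2 × 150 for the meta power-gain comparison;
100 discordant-effect pairs ($\pm 0.5$, 2 × 250) against a design-based
replicate oracle for triage; 200 enrichment replicates for calibration
and 100 for power; and a 10,000-variant null GWAS at 600 samples for
genomic inflation. Hidden factors and the expression floor are switched
off in scenarios that test estimation properties (they are exercised
separately), so that the estimand equals the planted value up to the
documented transform attenuation.

# Limitations

- Fixed-effects pooling only; random-effects and sample-size-weighted
  meta-analysis are out of scope, as are trans-eQTLs, interaction
  models, colocalization posteriors, LD-aware clumping with reference
  panels, and fine-mapping.
- The matched-null procedure controls MAF and TSS distance only — not
  GC content, LD, or gene density.
- Logistic fits use flag-and-exclude for separation rather than
  penalized regression, keeping estimates comparable with the
  closed-form contingency-table oracle.
- The generator's LD and confounder structure are chosen for
  testability, not biological realism; conclusions about real cohorts
  require the usual sensitivity analyses.

# A complete run

```{r example, eval = FALSE}
cfg <- simConfig(
  nSamples = c(tumor = 150, normal = 150), nVariants = 300, nGenes = 40,
  nCausalPairs = 5, betaCausal = 0.8, nRiskVariants = 3, riskOR = 2.5,
  riskOverlapFraction = 1, lowExprFraction = 0, seed = 11
)
res <- runPipeline(pipelineConfig(simulation = cfg), outDir = "run1")
res$candidates
```

`runPipeline()` executes simulate → QC → per-cohort eQTL → eQTL meta →
enrichment → GWAS → GWAS meta → integration → report, writing every
stage table (TSV) plus Manhattan/QQ/TSS-distance report tables and a
run manifest under `outDir`, and can resume from existing stage outputs
(`resume = TRUE`). Fixture sets round-trip through `writeFixtureSet()` /
`readFixtureSet()` as VCF (dosages in a `DS` FORMAT field), TSV and BED,
and are byte-identical under a fixed seed.
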