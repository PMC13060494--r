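---
title: "Rare-variant gene discovery and ancestry concentration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant gene discovery and ancestry concentration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radvar)
```

# Overview

`radvar` implements a gene-based rare-variant discovery pipeline of the kind
used in large multi-ancestry case-control sequencing studies of Alzheimer's
disease: consequence-mask construction from Sequence Ontology (SO)
annotations, covariate-adjusted gene-based association tests (burden, SKAT,
SKAT-O, ACAT-V, ACAT-O), carrier-based odds-ratio and trait-shift profiling,
ancestry-concentration metrics for rare alleles, and allele-age summary
comparisons. Because the genotype data such studies use is controlled-access,
the package ships a seeded synthetic cohort generator that reproduces the
statistical structure the analysis relies on, so every stage is exercised and
tested end to end on data anyone can regenerate.

# Consequence masks

Each variant carries one or more SO consequence terms. We keep the single
most severe term under a fixed 39-term severity order (`so_severity_order()`,
most severe first, from `transcript_ablation` down to `intergenic_variant`).
One deliberate quirk of the order implemented here: `splice_region_variant`
ranks *above* `splice_donor_5th_base_variant`, matching the order printed by
the study pipeline rather than the current VEP default. Masks are then defined
on the most severe term:

* **M1** — loss-of-function-like: transcript_ablation, stop_gained,
  frameshift_variant, stop_lost, start_lost, transcript_amplification;
* **M2** — protein-altering: inframe insertion/deletion, missense,
  protein_altering_variant;
* **M3** — splice-region: the six splice_* terms.

`transcript_amplification` appears in some published variants of the M1 list
and not others; it is included by default and removable via
`mask_definitions(include_amplification = FALSE)`.

A variant joins the qualifying set of gene *g* and mask *m* when it is
annotated to *g*, its most severe term lies in *m*, and its minor allele
frequency (MAF) is strictly below the threshold (default 0.01). Design
choices made where the convention is genuinely open:

* MAF is computed on the analysis samples (those with known case/control
  status), with missing genotypes excluded from numerator and denominator and
  allele frequencies above 0.5 folded. The analysis cohort is the only
  reference population always available.
* Masks are applied to the most severe term only (not to any matching term);
  this follows from retaining a single term per variant.
* A variant annotated to several genes enters each gene's sets independently,
  the standard gene-based testing convention.
* Missing genotypes count as non-carrier in all carrier-based analyses, a
  conservative choice that is flagged in outputs.

# Gene-based tests

All tests are covariate-adjusted score tests sharing one null model per
trait: logistic regression (IRLS) for case/control, least squares for
quantitative traits, with covariates age, sex, sequencing platform, PCR
status and 20 genetic PCs. The two-step whole-genome ridge used by some
production pipelines (REGENIE) is intentionally replaced by direct score
tests: at the scale this package targets there is no genome-wide common
variant panel to feed step 1, and the per-gene test structure is identical.

With dosages \(G\), weights \(w_j = \mathrm{Beta}(MAF_j; 1, 25)\) density,
residuals \(r = y - \hat\mu\) and covariate-adjusted score covariance \(V\):

* **Burden**: \(Z = w^\top G^\top r / \sqrt{w^\top V w}\), two-sided normal
  p-value, sign reported as the risk direction.
* **SKAT**: \(Q = \sum_j (w_j S_j)^2\), p-value from the eigenvalues of
  \(\mathrm{diag}(w)\, V\, \mathrm{diag}(w)\) via `davies_pvalue()`.
* **SKAT-O**: \(Q_\rho = (1-\rho) Q_{SKAT} + \rho Q_{burden}\) over the grid
  \(\{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}\), combined by the
  minimum-p procedure (conditioning on the shared burden direction and
  integrating over a one-dimensional chi-square).
* **ACAT-V**: per-variant score p-values for variants with minor allele count
  above 10, the ultra-rare remainder collapsed into one burden component,
  combined by the Cauchy transform with weights \(w_j^2 MAF_j (1-MAF_j)\).
* **ACAT-O**: equal-weight Cauchy combination of burden, SKAT and ACAT-V
  within one gene-mask.

The weights, the SKAT-O grid and the MAC-10 collapse threshold follow the
original SKAT/ACAT publications; the study this package models does not state
its choices, so all three are configurable arguments rather than constants.

## Numerical choices

`davies_pvalue()` computes \(P(\sum_k \lambda_k \chi^2_1 > q)\) by Imhof-type
characteristic-function inversion: the oscillatory integral is evaluated by
vectorized Gauss-Legendre quadrature over chunks of a few oscillation
periods, truncated where either the non-oscillatory envelope bound or the
residual of a two-term integration-by-parts expansion drops below the target
accuracy (1e-10 by default). One eigenvalue is routed to the exact chi-square
tail. Below p = 1e-9 the inversion's absolute error is dominated by
oscillatory cancellation and the Kuonen saddlepoint approximation is used
instead (excellent relative accuracy in the far tail). The Liu et al.
moment-matched approximation is the fallback whenever inversion is
unavailable, and p-values are floored at 1e-300. The Cauchy combination
guards its transform at both ends (stabilized tails below 1e-16 and at or
above 0.999).

Degenerate inputs are errors, not silent results: a qualifying set whose
collapsed burden has zero variance, an empty rho grid, a p-value of exactly 0
passed to the Cauchy combiner.

## Type-I behaviour worth knowing

Score tests on ultra-rare variants are slightly conservative at moderate
sample sizes with binary outcomes: the score contribution of a singleton is
a two-point random variable, and the normal / chi-square-mixture reference
distributions overstate moderate tail mass. In the package's calibration
suite (n = 1,000 samples, gene-mask sets of realistic size) burden, ACAT-V,
ACAT-O and SKAT-O sit inside 3 binomial SEs of the nominal 0.05 level; SKAT,
whose Beta(1,25)^2 weights concentrate on the rarest variants, hovers at the
conservative edge of that band (~0.035-0.04). This is the documented
small-sample behaviour of unadjusted SKAT with binary traits, not an
implementation artifact; production implementations add small-sample moment
adjustments that are out of scope here.

# Carrier analyses

A carrier is a sample with at least one qualifying allele in the gene. Odds
ratios come from the 2x2 carrier-by-phenotype table with a Wald CI on the log
scale; when any cell is zero, the Haldane-Anscombe correction adds 0.5 to all
four cells first (flagged). Ancestry-stratified ORs are computed within
strata and pooled by joint counts (not meta-analysis); strata with no cases
or no controls are skipped with a warning.

Trait comparisons use two-sided Wilcoxon rank-sum tests with Hodges-Lehmann
location shifts (median of all pairwise carrier-minus-non-carrier
differences) for quantitative and ordinal traits, and Fisher's exact test
with an odds ratio for binary traits. Ordinal neuropathology stages (Braak,
CERAD, Lewy body stage, arteriolo-/atherosclerosis grades) are treated as
numeric ranks. The exact Wilcoxon null is enumerated when both groups have at
most 25 observations and no ties; otherwise the normal approximation with tie
and continuity correction is used. `Age_AmongCase` is the age comparison
restricted to cases. Each gene-trait cell receives a direction-standardized
signed score \(\pm\log_{10} p\): positive when carriers shift toward the
adverse direction, where adversity is *lower* values for Age, Age_AmongCase,
MEM, EXF, LAN, VSP and CSF Abeta42, and *higher* values for every other trait
in the default panel. Cells with fewer than five carriers are computed but
flagged, never suppressed; no multiplicity correction is applied within this
module.

# Ancestry concentration

Per variant (restricted to variants with at least two carriers), carriers are
counted by case/control status and by ancestry label; samples with unknown
status contribute to ancestry composition but not to the case/control cells.
A variant is **AD-enriched** with >= 2 case carriers and either no control
carriers or a case/control carrier ratio >= 1 (meaningful because it exceeds
the cohort's own case/control ratio, which is recomputed from the data, never
hard-coded), and **AD-skew** with >= 5 case carriers and ratio >= 5; AD-skew
implies AD-enriched, and the more specific label is reported. Concentration
metrics are the dominant-ancestry proportion (max carrier share in one
ancestry; >= 75% defines "single-ancestry-like", ties broken to the
lexicographically smallest label) and the Gini-Simpson diversity
\(D = 1 - \sum_i p_i^2\). The Gini-Simpson orientation was chosen because the
analysis reads lower values as lower ancestry mixture; the raw Simpson
concentration \(\sum p_i^2\) is a trivial reparameterization if preferred.
Group comparisons report medians, Wilcoxon p-values and single-ancestry-like
fractions, both as two groups (AD-enriched including AD-skew versus other)
and as three display groups.

# Allele ages

Coalescent allele-age estimation itself (RELATE-style inference, proxy
selection, background-set construction) is out of scope; the module consumes
a table of point estimates with CI bounds, in generations. Quality filtering
retains records with CI ratio at most 10 and age at most 500,000 generations.
"CI ratio" is not defined by the source analysis; it is implemented as
upper/lower bound ratio because that reading is scale-free, and it is
configurable. Records with a zero lower bound are tallied separately rather
than crashing, each rejected record is tallied exactly once, and filtering is
idempotent. Group comparisons report per-group medians and Wilcoxon p-values,
optionally stratified by allele-frequency bin.

# The synthetic cohort generator

`simulate_cohort()` generates the world the analysis assumes, not the world
sequencing produces. What it emulates, with defaults chosen once:

* **Composition**: five major ancestry groups at the published cohort's
  proportions, scaled to 5,000 samples by default; per-ancestry case and
  control fractions follow the published per-ancestry table, the remainder
  having unknown status.
* **Rare tail**: per-variant carrier counts follow a truncated geometric
  tuned so 51.39% of variants are singletons; 2.58% of variants are simulated
  common (MAF > 0.01) so that 97.42% fall below the 1% threshold. Carriers
  are heterozygous with a small (0.5%) homozygote rate.
* **Ancestry concentration**: with probability 0.54 a rare variant's carriers
  are drawn from a single ancestry (sampled proportionally to ancestry size),
  otherwise from the whole cohort; planted genes can be given their own
  concentration probability.
* **Planted effects**: case status follows
  \(P(\text{case} \mid g, a) = \mathrm{logit}^{-1}(\alpha_a + \sum \beta g)\),
  with \(\alpha_a\) the ancestry baseline and the sum over planted
  (gene, mask) qualifying dosages, so a planted \(\beta\) is an exact
  per-allele carrier log-odds ratio.
* **Covariates and traits**: PCs are ancestry-shifted Gaussians so null-model
  adjustment is genuinely exercised; platform/PCR/sex are Bernoulli.
  Quantitative traits are baseline + case shift + carrier shift + Gaussian
  noise; ordinal traits threshold the same latent variable; binary traits use
  a logistic link. Trait missingness (30% by default) mirrors the sparse
  availability of harmonized endophenotypes.
* **Ages**: a parametric stand-in (lognormal around a frequency-dependent
  median, so rarer alleles are younger), not a demographic model.

What it does **not** emulate: linkage disequilibrium and haplotype structure,
sequence context, relatedness, genotyping error correlated with ancestry, or
a realistic coalescent. A green test therefore establishes that the
*statistics* behave as specified on data with the assumed structure — it says
nothing about robustness to LD between qualifying variants or to population
structure beyond what 20 ancestry-shifted PCs capture.

Determinism: one master seed drives named sub-streams (genotypes,
phenotypes, traits, ages), so identical configurations yield byte-identical
output files, and regenerating one component does not perturb the others.
Genotype missingness (0.1%) is applied to non-carrier cells only, keeping the
stated carrier structure exact.

The per-gene variant count used in the type-I calibration suite (mean 50) is
chosen to mirror the qualifying-set sizes reported for the study's
significant gene-mask pairs (tens to hundreds of variants); two-variant
singleton-only sets are valid inputs but their discrete score support makes
a 5% rejection rate unattainable at any implementation quality. Similarly,
the ancestry-concentration recovery suite profiles variants with at least
three carriers rather than two: at a few thousand samples, most two-carrier
variants have a dominant-ancestry proportion of exactly 0.5 or 1, and the
group medians tie; at the original cohort's scale the two-carrier
restriction carries more information.

# Limitations

* No LD: aggregation-test eigenstructure under real LD is untested here.
* No small-sample moment adjustment for SKAT with binary traits (see above).
* Covariate-adjusted trait models for the gene-trait cells are deliberately
  out of scope; the cells are marginal carrier comparisons.
* The Bonferroni denominator defaults to genes actually tested in a run and
  must be overridden (`n_genes_for_threshold`) to reproduce a fixed
  genome-wide denominator such as 30,276.
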