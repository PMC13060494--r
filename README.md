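# radvar

Gene-based rare-variant discovery and carrier profiling for multi-ancestry
case-control sequencing studies.

Large whole-genome sequencing cohorts for Alzheimer's disease hunt for genes
in which **rare coding or splice variants** (MAF < 1%) aggregate differently
between cases and controls. Because no single rare variant carries enough
carriers to test on its own, variants are pooled per gene within
annotation-defined **masks** — loss-of-function-like (M1), protein-altering
(M2), splice-region (M3), built from the most severe Sequence Ontology
consequence per variant — and the pooled set is tested with complementary
covariate-adjusted score tests:

* **burden** — `Z = wᵀGᵀ(y−μ̂) / √(wᵀVw)`, powerful when effects share a
  direction, and directionally interpretable;
* **SKAT** — quadratic form `Q = Σⱼ (wⱼSⱼ)²` against a weighted chi-square
  mixture, robust to mixed effect directions;
* **SKAT-O** — optimal convex combination `Qρ = (1−ρ)Q_SKAT + ρQ_burden`;
* **ACAT-V / ACAT-O** — Cauchy combinations `T = Σ w̃ⱼ tan((0.5−pⱼ)π)`,
  robust to sparse strong effects;

with weights `wⱼ = Beta(MAFⱼ; 1, 25)` and covariates age, sex, platform, PCR
status and 20 genetic PCs. Downstream, the package profiles **carriers**
(ancestry-stratified odds ratios with Haldane-Anscombe correction; Wilcoxon /
Hodges-Lehmann and Fisher tests against AD-related traits with
direction-standardized signed scores), classifies rare variants by **AD
enrichment and ancestry concentration** (dominant-ancestry proportion,
Gini-Simpson diversity `D = 1 − Σpᵢ²`), and summarizes **allele-age** tables
(CI-ratio ≤ 10 and age ≤ 500,000 generations quality filters, group
comparisons).

Real cohorts of this kind are controlled-access, so the package ships a
seeded **synthetic cohort generator** reproducing the statistical structure
the analysis needs — multi-ancestry composition, a singleton-heavy rare tail
(51.4% singletons, 97.4% of variants below 1% MAF), ancestry-concentrated
carriers, planted risk/protective genes with exact per-allele log-odds
effects, and case/carrier-shifted traits — making every stage testable end
to end. See `vignettes/radvar-methods.Rmd` for the model details and design
rationale.

## Worked example

```r
library(radvar)

cfg <- cohort_config(
  n_per_ancestry = c(AFRAM = 550, EAS = 260, EUR = 2580, LAT1 = 700, LAT2 = 440),
  n_genes = 40, variants_per_gene = list(mean = 20),
  planted_genes = data.frame(gene = "G0007", mask = "M2", beta = log(3)),
  seed = 2026)
cohort <- simulate_cohort(cfg)
cohort
#> <radvar_cohort> 4530 samples (5 ancestries), 794 variants in 40 genes

known <- !is.na(cohort$samples$status)       # analysis samples
G <- cohort$genotypes[known, , drop = FALSE]
sets <- build_qualifying_sets(annotate_variants(cohort$annotations, G), G,
                              maf_threshold = 0.01)
null <- fit_null(cohort$samples$status[known],
                 as.matrix(cohort$samples[known, c("age", "sex", "platform",
                                                   "pcr", paste0("PC", 1:20))]),
                 kind = "binary")
results <- run_gene_tests(sets, null)

s <- sets[["G0007:M2"]]                      # the planted risk gene
est <- odds_ratio_wald(carrier_table(carrier_status(s), null$y))
sprintf("G0007 carrier OR %.2f (95%% CI %.2f-%.2f)", est$or, est$ci_lower, est$ci_upper)
#> "G0007 carrier OR 2.73 (95% CI 1.21-6.16)"

prof <- build_profiles(cohort$genotypes, cohort$samples$status,
                       cohort$samples$ancestry, min_carriers = 2)
compare_concentration(prof)$two_group
#>         group   n median_dominant median_simpson frac_single_ancestry_like
#> 1 AD-enriched  65               1              0                     0.769
#> 2       other 340               1              0                     0.674

signif(bonferroni_threshold(0.05, 40), 3)
#> 0.00125
```

The planted gene's carrier odds ratio recovers its per-allele effect
(`exp(ln 3) = 3`, estimated 2.73 with a CI containing 3). The
ancestry-concentration table shows AD-enriched variants more often
single-ancestry-like than the background (76.9% vs 67.4%), the pattern the
concentration module is built to quantify. `results` is the long table of
per-(gene, mask) p-values for every test, sorted by p and compared against
`bonferroni_threshold(alpha, n_genes)`.

One call runs everything (simulate → mask → test → carrier/trait profiles →
concentration → ages) and writes stage TSVs plus a JSON manifest:

```r
run_pipeline(pipeline_config(mode = "simulate", cohort = cfg), "out/")
```

A YAML-driven command-line interface with the same stages lives in
`inst/cli/radvar.R`.

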