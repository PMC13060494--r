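# shared fixtures built in code

# hand-built qualifying set from a dosage matrix
make_set <- function(G, gene = "GX", mask = "M2", maf = NULL, weights = NULL) {
  G <- as.matrix(G)
  if (is.null(colnames(G))) colnames(G) <- paste0("v", seq_len(ncol(G)))
  if (is.null(maf)) {
    maf <- allele_stats(G)$maf
  }
  if (is.null(weights)) weights <- rep(1, ncol(G))
  radvar:::new_qv_set(gene = gene, mask = mask, G = G, maf = maf,
                      weights = weights, variant_ids = colnames(G))
}

# small balanced case/control cohort config with no unknown-status samples
balanced_config <- function(n_case = 2000, n_control = 2000, n_genes = 10,
                            vpg = 20, planted = NULL, seed = 1, ...) {
  n <- n_case + n_control
  cohort_config(
    n_per_ancestry = c(POPA = ceiling(n * 0.6), POPB = floor(n * 0.4)),
    case_fraction_per_ancestry = c(POPA = n_case / n, POPB = n_case / n),
    control_fraction_per_ancestry = c(POPA = 1 - n_case / n,
                                      POPB = 1 - n_case / n),
    n_genes = n_genes, variants_per_gene = list(mean = vpg),
    planted_genes = planted, seed = seed, ...)
}

# null model + qualifying sets for a simulated cohort, analysis samples only
fit_cohort <- function(cohort, maf_threshold = 0.01) {
  known <- !is.na(cohort$samples$status)
  G <- cohort$genotypes[known, , drop = FALSE]
  sets <- build_qualifying_sets(annotate_variants(cohort$annotations, G), G,
                                maf_threshold = maf_threshold)
  X <- as.matrix(cohort$samples[known, c("age", "sex", "platform", "pcr",
                                         paste0("PC", 1:20))])
  list(known = known, G = G, sets = sets,
       null = fit_null(cohort$samples$status[known], X, "binary"))
}

# exact two-sided Wilcoxon rank-sum p by enumeration of all splits
wilcox_enum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  combs <- utils::combn(length(pooled), length(x))
  stats_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# exact two-sided Fisher p by hypergeometric enumeration over all tables
fisher_enum_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}
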