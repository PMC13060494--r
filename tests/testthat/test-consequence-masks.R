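test_that("severity order has the full vocabulary with unique ranks", {
  ord <- so_severity_order()
  expect_length(ord, 39L)
  expect_false(anyDuplicated(ord) > 0)
  expect_identical(ord[1:4], c("transcript_ablation", "splice_acceptor_variant",
                               "splice_donor_variant", "stop_gained"))
  expect_identical(ord[length(ord)], "intergenic_variant")
  # this ordering places splice_region above splice_donor_5th_base
  expect_lt(match("splice_region_variant", ord),
            match("splice_donor_5th_base_variant", ord))
})

test_that("most_severe picks the minimal rank and ignores input order", {
  expect_identical(most_severe(c("stop_gained", "missense_variant")),
                   "stop_gained")
  expect_identical(most_severe(c("missense_variant", "splice_region_variant")),
                   "missense_variant")
  expect_identical(most_severe("intergenic_variant"), "intergenic_variant")
  # invariance to permutation, property over random subsets
  ord <- so_severity_order()
  set.seed(42)
  for (i in 1:50) {
    terms <- sample(ord, sample(1:6, 1))
    expect_identical(most_severe(terms), most_severe(rev(terms)))
    expect_identical(most_severe(sample(terms)),
                     ord[min(match(terms, ord))])
  }
  expect_error(most_severe(character(0)), "non-empty")
  expect_error(most_severe("made_up_term"), "made_up_term")
})

test_that("mask definitions are disjoint and assign_mask is total", {
  masks <- mask_definitions()
  expect_setequal(masks$M1, c("transcript_ablation", "stop_gained",
                              "frameshift_variant", "stop_lost", "start_lost",
                              "transcript_amplification"))
  expect_setequal(masks$M2, c("inframe_insertion", "inframe_deletion",
                              "missense_variant", "protein_altering_variant"))
  expect_setequal(masks$M3, c("splice_acceptor_variant", "splice_donor_variant",
                              "splice_donor_5th_base_variant",
                              "splice_region_variant",
                              "splice_donor_region_variant",
                              "splice_polypyrimidine_tract_variant"))
  expect_length(intersect(masks$M1, masks$M2), 0)
  expect_length(intersect(masks$M1, masks$M3), 0)
  expect_length(intersect(masks$M2, masks$M3), 0)

  expect_identical(assign_mask("missense_variant"), "M2")
  expect_identical(assign_mask("splice_donor_5th_base_variant"), "M3")
  expect_identical(assign_mask("synonymous_variant"), "none")
  # total over the whole vocabulary, each term in at most one mask
  for (term in so_severity_order()) {
    hits <- sum(vapply(masks, function(m) term %in% m, logical(1)))
    expect_lte(hits, 1L)
    expect_identical(assign_mask(term),
                     if (hits == 0) "none" else
                       names(masks)[vapply(masks, function(m)
                         term %in% m, logical(1))])
  }
  expect_false("transcript_amplification" %in%
                 mask_definitions(include_amplification = FALSE)$M1)
})

test_that("multi-allelic decomposition conserves per-sample allele dosage", {
  bi <- list(chrom = "1", pos = 100L, id = "v1", ref = "A", alt = "T",
             gt = c("0/1", "0/0", "1/1", "./."))
  out <- decompose_multiallelic(bi)
  expect_length(out, 1L)
  expect_identical(out[[1]]$dosage, c(1L, 0L, 2L, NA_integer_))

  tri <- list(chrom = "1", pos = 200L, id = "v2", ref = "A", alt = c("T", "G"),
              gt = c("1/2", "2/2", "0/1", "0/0", "1|1"))
  out <- decompose_multiallelic(tri)
  expect_length(out, 2L)
  # allele-count bookkeeping oracle: GT 1/2 -> one of each; 2/2 -> (0, 2)
  expect_identical(out[[1]]$dosage, c(1L, 0L, 1L, 0L, 2L))
  expect_identical(out[[2]]$dosage, c(1L, 2L, 0L, 0L, 0L))
  # conservation of total alternate dosage per sample
  tot <- out[[1]]$dosage + out[[2]]$dosage
  expect_identical(tot, c(2L, 2L, 1L, 0L, 2L))

  expect_error(
    decompose_multiallelic(list(chrom = "1", pos = 1L, id = "x", ref = "A",
                                alt = "T", gt = c("0/1", "0/5"))),
    "malformed genotype")
})

test_that("random multi-allelic records conserve dosage (property)", {
  set.seed(7)
  for (rep in 1:20) {
    n_alt <- sample(2:4, 1); n_samp <- sample(3:8, 1)
    gt <- replicate(n_samp, {
      if (runif(1) < 0.1) "./." else
        paste(sample(0:n_alt, 2, replace = TRUE), collapse = "/")
    })
    rec <- list(chrom = "1", pos = 1L, id = "v", ref = "A",
                alt = LETTERS[seq_len(n_alt)], gt = gt)
    out <- decompose_multiallelic(rec)
    expect_length(out, n_alt)
    tot <- Reduce(`+`, lapply(out, `[[`, "dosage"))
    expected <- vapply(gt, function(g) {
      if (g == "./.") return(NA_integer_)
      sum(as.integer(strsplit(g, "/")[[1]]) > 0L)
    }, integer(1), USE.NAMES = FALSE)
    expect_identical(tot, expected)
  }
})

test_that("allele stats fold AF and handle missing genotypes", {
  G <- cbind(v1 = c(0, 1, 2, NA), v2 = c(2, 2, 2, 1), v3 = c(0, 0, NA, NA))
  st <- allele_stats(G)
  expect_equal(st$ac, c(3, 7, 0), ignore_attr = TRUE)
  expect_equal(st$an, c(6, 8, 4), ignore_attr = TRUE)
  expect_equal(st$af, c(0.5, 7 / 8, 0), ignore_attr = TRUE)
  expect_equal(st$maf, c(0.5, 1 / 8, 0), ignore_attr = TRUE)
})

test_that("qualifying sets enforce strict MAF bound and drop empties", {
  n <- 300
  set.seed(3)
  G <- cbind(rare = rbinom(n, 1, 0.004),          # MAF well below 0.01
             at_threshold = c(rep(1, 2 * n * 0.01 / 2), rep(0, n))[1:n],
             common = rbinom(n, 2, 0.3),
             benign = rbinom(n, 1, 0.003))
  # force MAF exactly 0.01 for the at_threshold column
  G[, "at_threshold"] <- 0
  G[seq_len(n * 0.02), "at_threshold"] <- 1
  anno <- data.frame(
    variant_id = colnames(G),
    gene = c("GA", "GA", "GA", "GB"),
    consequence_terms = c("missense_variant", "missense_variant",
                          "stop_gained", "synonymous_variant"))
  ann <- annotate_variants(anno, G)
  expect_equal(ann$maf[ann$variant_id == "at_threshold"], 0.01)
  sets <- build_qualifying_sets(ann, G, maf_threshold = 0.01)
  # MAF 0.01 excluded (strict), common excluded, benign mask none -> GB absent
  expect_named(sets, "GA:M2")
  expect_identical(sets[["GA:M2"]]$variant_ids, "rare")
  # variant with MAF 0.02 excluded at threshold 0.01
  G2 <- cbind(v = c(rep(1, 12), rep(0, 288)))
  ann2 <- annotate_variants(
    data.frame(variant_id = "v", gene = "G1",
               consequence_terms = "missense_variant"), G2)
  expect_length(build_qualifying_sets(ann2, G2, 0.01), 0)
  expect_named(build_qualifying_sets(ann2, G2, 0.05), "G1:M2")
})

test_that("multi-gene annotations contribute to each gene independently", {
  G <- cbind(v1 = c(1, 0, 0, 0, rep(0, 196)))
  anno <- data.frame(variant_id = c("v1", "v1"), gene = c("GA", "GB"),
                     consequence_terms = "missense_variant")
  sets <- build_qualifying_sets(annotate_variants(anno, G), G)
  expect_setequal(names(sets), c("GA:M2", "GB:M2"))
})

test_that("a variant lands in at most one (gene, mask) set per gene", {
  cfg <- balanced_config(n_case = 200, n_control = 200, n_genes = 20, vpg = 10)
  coh <- simulate_cohort(cfg)
  f <- fit_cohort(coh)
  for (g in unique(vapply(f$sets, `[[`, character(1), "gene"))) {
    ids <- unlist(lapply(f$sets[vapply(f$sets, function(s) s$gene == g,
                                       logical(1))], `[[`, "variant_ids"))
    expect_false(anyDuplicated(ids) > 0)
  }
})
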