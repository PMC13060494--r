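#' Synthetic multi-ancestry cohort configuration
#'
#' Declares the statistical world the generator emulates: multi-ancestry
#' sample composition with per-ancestry case/control/unknown fractions, a
#' heavy rare tail (singleton-dominated carrier counts, almost all variants
#' with MAF < 0.01), ancestry-concentrated carrier draws, planted
#' risk/protective genes acting through a per-allele logistic model, and
#' case- and carrier-shifted AD-related traits.
#'
#' Defaults mirror the composition of a large multi-ancestry AD sequencing
#' cohort scaled down to 5,000 samples across the five major ancestry groups
#' (ancestry shares and per-ancestry case/control fractions follow the
#' published cohort table), a 51.39% singleton fraction, 2.58% of variants
#' common (so 97.42% have MAF < 0.01), and a 0.54 probability that a rare
#' variant's carriers are drawn from a single ancestry.
#'
#' @param n_per_ancestry Named integer vector: samples per ancestry label.
#' @param case_fraction_per_ancestry Named vector in [0,1]; fraction of each
#'   ancestry that is an AD case.
#' @param control_fraction_per_ancestry Named vector in [0,1]; remaining
#'   samples have unknown status. Defaults to published per-ancestry control
#'   shares (or 1 - case fraction where not supplied).
#' @param n_genes Number of genes.
#' @param variants_per_gene List with \code{mean}: variant count per gene is
#'   1 + Poisson(mean - 1).
#' @param planted_genes data.frame with columns gene (id such as "G0001"),
#'   mask ("M1"/"M2"/"M3"), beta (per-allele log-odds; > 0 risk,
#'   < 0 protective). NULL for a null cohort.
#' @param ancestry_concentration Probability a rare variant's carriers all
#'   come from one ancestry.
#' @param planted_ancestry_concentration Same probability for variants in
#'   planted genes (default: equal to \code{ancestry_concentration}).
#' @param singleton_fraction_target Target fraction of variants with exactly
#'   one carrier chromosome.
#' @param common_variant_fraction Fraction of variants simulated with
#'   MAF > 0.01 (excluded downstream by the MAF filter).
#' @param trait_specs data.frame of simulated traits: name, kind
#'   ("binary"/"quantitative"/"ordinal"), baseline, sd, case_shift,
#'   carrier_shift. See [default_sim_traits()].
#' @param missing_rate Genotype missingness rate (applied to non-carrier
#'   cells so carrier structure stays as stated).
#' @param hom_rate Probability a rare-variant carrier is homozygous.
#' @param trait_missing_rate Per-trait per-sample missingness.
#' @param seed Integer master seed; named sub-streams are derived for
#'   genotypes, phenotypes and ages.
#' @return List of class \code{cohort_config}.
#' @export
cohort_config <- function(n_per_ancestry = c(AFRAM = 550, EAS = 260,
                                             EUR = 2580, LAT1 = 700,
                                             LAT2 = 440),
                          case_fraction_per_ancestry = c(AFRAM = 0.242,
                                                         EAS = 0.352,
                                                         EUR = 0.259,
                                                         LAT1 = 0.289,
                                                         LAT2 = 0.153),
                          control_fraction_per_ancestry = c(AFRAM = 0.513,
                                                            EAS = 0.510,
                                                            EUR = 0.443,
                                                            LAT1 = 0.543,
                                                            LAT2 = 0.624),
                          n_genes = 50,
                          variants_per_gene = list(mean = 8),
                          planted_genes = NULL,
                          ancestry_concentration = 0.54,
                          planted_ancestry_concentration = NULL,
                          singleton_fraction_target = 0.5139,
                          common_variant_fraction = 0.0258,
                          trait_specs = default_sim_traits(),
                          missing_rate = 0.001,
                          hom_rate = 0.005,
                          trait_missing_rate = 0.3,
                          seed = 1L) {
  anc <- names(n_per_ancestry)
  if (is.null(anc) || anyDuplicated(anc)) {
    stop("n_per_ancestry must have unique names")
  }
  case_fraction_per_ancestry <- case_fraction_per_ancestry[anc]
  control_fraction_per_ancestry <- control_fraction_per_ancestry[anc]
  case_fraction_per_ancestry[is.na(case_fraction_per_ancestry)] <- 0
  control_fraction_per_ancestry[is.na(control_fraction_per_ancestry)] <-
    (1 - case_fraction_per_ancestry)[is.na(control_fraction_per_ancestry)]
  if (is.null(planted_ancestry_concentration)) {
    planted_ancestry_concentration <- ancestry_concentration
  }
  frac <- c(case_fraction_per_ancestry, control_fraction_per_ancestry,
            ancestry_concentration, planted_ancestry_concentration,
            singleton_fraction_target,
            common_variant_fraction, missing_rate, hom_rate,
            trait_missing_rate)
  if (any(n_per_ancestry < 0) || n_genes < 0 ||
      any(frac < 0) || any(frac > 1) ||
      any(case_fraction_per_ancestry + control_fraction_per_ancestry > 1 + 1e-12)) {
    stop("configuration error: counts must be >= 0 and fractions in [0,1]")
  }
  if (any(n_per_ancestry == 0 & case_fraction_per_ancestry > 0)) {
    stop("configuration error: zero samples in an ancestry with nonzero case fraction")
  }
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(planted_genes)) {
    planted_genes <- as.data.frame(planted_genes)
    if (!all(c("gene", "mask", "beta") %in% names(planted_genes))) {
      stop("planted_genes needs columns gene, mask, beta")
    }
    if (!all(planted_genes$gene %in% gene_ids)) {
      stop("configuration error: planted gene id not among generated genes")
    }
    if (!all(planted_genes$mask %in% c("M1", "M2", "M3"))) {
      stop("configuration error: planted gene references unknown mask id")
    }
  }
  structure(list(
    n_per_ancestry = n_per_ancestry,
    case_fraction_per_ancestry = case_fraction_per_ancestry,
    control_fraction_per_ancestry = control_fraction_per_ancestry,
    n_genes = n_genes, gene_ids = gene_ids,
    variants_per_gene = variants_per_gene,
    planted_genes = planted_genes,
    ancestry_concentration = ancestry_concentration,
    planted_ancestry_concentration = planted_ancestry_concentration,
    singleton_fraction_target = singleton_fraction_target,
    common_variant_fraction = common_variant_fraction,
    trait_specs = trait_specs,
    missing_rate = missing_rate, hom_rate = hom_rate,
    trait_missing_rate = trait_missing_rate,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Default simulated trait panel
#'
#' Quantitative traits are baseline + case_shift * case + carrier_shift *
#' carrier + Gaussian noise; ordinal traits threshold the same latent Gaussian
#' into 0..6; binary traits pass the latent through a logistic link around the
#' baseline prevalence. Carrier means carrier of any planted qualifying
#' variant. Shifts are oriented adversely (cases score worse on each trait's
#' adverse direction).
#'
#' @return data.frame: name, kind, baseline, sd, case_shift, carrier_shift.
#' @export
default_sim_traits <- function() {
  data.frame(
    name = c("Age", "MEM", "EXF", "Abeta42", "Braak", "CERAD", "HS_S", "TDP43"),
    kind = c("quantitative", "quantitative", "quantitative", "quantitative",
             "ordinal", "ordinal", "binary", "binary"),
    baseline = c(78, 0, 0, 800, 2, 1.5, 0.08, 0.1),
    sd = c(8, 1, 1, 180, 1.4, 1.2, NA, NA),
    case_shift = c(-3, -0.9, -0.7, -160, 1.3, 1.1, 1.0, 0.9),
    carrier_shift = c(-1.5, -0.3, -0.2, -60, 0.5, 0.4, 0.4, 0.3),
    stringsAsFactors = FALSE)
}

# deterministic sub-stream seeds, kept below 2^31
substream_seed <- function(seed, component) {
  offsets <- c(genotypes = 101L, annotations = 211L, phenotypes = 307L,
               traits = 401L, ages = 503L)
  (as.integer(seed) * 1009L + offsets[[component]]) %% .Machine$integer.max
}

#' Simulate a synthetic multi-ancestry cohort
#'
#' Generates genotypes, annotations, phenotypes (status, covariates, 20
#' ancestry-shifted PCs, traits) and a parametric allele-age table under the
#' configured world. Case status follows the per-allele logistic model
#' \eqn{P(case | g, a) = logit^{-1}(\alpha_a + \sum \beta g)} where
#' \eqn{\alpha_a} is the ancestry baseline and the sum runs over planted
#' (gene, mask) qualifying dosages. Identical config + seed gives identical
#' output (and byte-identical files via [write_cohort()]).
#'
#' @param config A \code{cohort_config}.
#' @return List of class \code{radvar_cohort}: samples (data.frame),
#'   genotypes (samples x variants matrix, NA = missing), annotations
#'   (variant_id, gene, consequence_terms), ages (variant_id, group, age,
#'   lower, upper), config.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  anc_n <- config$n_per_ancestry
  anc <- rep(names(anc_n), anc_n)
  n <- length(anc)
  if (n == 0L) stop("configuration error: empty cohort")
  sample_ids <- sprintf("S%05d", seq_len(n))

  geno <- withr::with_seed(substream_seed(config$seed, "genotypes"),
                           sim_genotypes(config, anc, sample_ids))
  pheno <- withr::with_seed(substream_seed(config$seed, "phenotypes"),
                            sim_phenotypes(config, anc, sample_ids, geno))
  traits <- withr::with_seed(substream_seed(config$seed, "traits"),
                             sim_traits(config, pheno$status, geno$planted_carrier))
  ages <- withr::with_seed(substream_seed(config$seed, "ages"),
                           sim_ages(config, geno))
  samples <- cbind(pheno$samples, traits)
  structure(list(samples = samples, genotypes = geno$G,
                 annotations = geno$annotations, ages = ages,
                 variant_meta = geno$meta, config = config),
            class = "radvar_cohort")
}

#' @export
print.radvar_cohort <- function(x, ...) {
  cat(sprintf("<radvar_cohort> %d samples (%d ancestries), %d variants in %d genes\n",
              nrow(x$samples), length(unique(x$samples$ancestry)),
              ncol(x$genotypes), length(unique(x$annotations$gene))))
  invisible(x)
}

benign_terms <- function() {
  c("synonymous_variant", "intron_variant", "5_prime_UTR_variant",
    "3_prime_UTR_variant", "upstream_gene_variant", "downstream_gene_variant",
    "intergenic_variant", "non_coding_transcript_exon_variant")
}

sim_genotypes <- function(config, anc, sample_ids) {
  n <- length(anc)
  masks <- mask_definitions()
  order <- so_severity_order()
  n_var_gene <- 1L + stats::rpois(config$n_genes,
                                  max(0, config$variants_per_gene$mean - 1))
  gene_of <- rep(config$gene_ids, n_var_gene)
  m <- length(gene_of)
  variant_ids <- sprintf("V%05d", seq_len(m))
  chrom <- 1L + (match(gene_of, config$gene_ids) - 1L) %% 22L
  pos <- integer(m)
  for (g in unique(gene_of)) {
    idx <- which(gene_of == g)
    pos[idx] <- 1e6L * ((match(g, config$gene_ids) - 1L) %/% 22L + 1L) +
      seq_along(idx) * 50L
  }

  planted <- config$planted_genes
  intent <- character(m)
  for (j in seq_len(m)) {
    pm <- if (!is.null(planted) && gene_of[j] %in% planted$gene) {
      planted$mask[match(gene_of[j], planted$gene)]
    } else NA_character_
    intent[j] <- if (!is.na(pm) && stats::runif(1) < 0.8) pm else {
      sample(c("M1", "M2", "M3", "none"), 1,
             prob = c(0.12, 0.55, 0.18, 0.15))
    }
  }
  term_pool <- c(masks, list(none = benign_terms()))
  terms <- vapply(intent, function(it) sample(term_pool[[it]], 1), character(1))
  # extra, strictly less severe terms on ~20% of variants
  extra <- vapply(seq_len(m), function(j) {
    if (stats::runif(1) >= 0.2) return("")
    rank <- match(terms[[j]], order)
    if (rank >= length(order)) return("")
    paste(sample(order[(rank + 1L):length(order)],
                 min(1L + stats::rbinom(1, 1, 0.4), length(order) - rank)),
          collapse = ",")
  }, character(1))
  all_terms <- ifelse(extra == "", terms, paste(terms, extra, sep = ","))

  # carrier counts: mixture of a common component and a singleton-heavy
  # truncated geometric for the rare tail
  rare_singleton_p <- min(1, config$singleton_fraction_target /
                            max(1e-9, 1 - config$common_variant_fraction))
  kmax <- max(1L, as.integer(floor(0.0195 * n)))
  is_common <- stats::runif(m) < config$common_variant_fraction
  anc_sizes <- config$n_per_ancestry

  G <- matrix(0L, n, m, dimnames = list(sample_ids, variant_ids))
  for (j in seq_len(m)) {
    if (is_common[j]) {
      maf <- stats::runif(1, 0.012, 0.2)
      G[, j] <- stats::rbinom(n, 2L, maf)
      next
    }
    k <- min(1L + stats::rgeom(1, rare_singleton_p), kmax)
    conc_p <- if (!is.null(planted) && gene_of[j] %in% planted$gene) {
      config$planted_ancestry_concentration
    } else {
      config$ancestry_concentration
    }
    conc <- stats::runif(1) < conc_p
    carriers <- if (conc) {
      elig <- names(anc_sizes)[anc_sizes >= k]
      if (!length(elig)) {
        sample.int(n, k)
      } else {
        a <- sample(elig, 1, prob = anc_sizes[elig])
        sample(which(anc == a), k)
      }
    } else {
      sample.int(n, k)
    }
    dos <- 1L + stats::rbinom(length(carriers), 1L, config$hom_rate)
    G[carriers, j] <- dos
  }
  if (config$missing_rate > 0) {
    zero <- which(G == 0L)
    nm <- stats::rbinom(1, length(zero), config$missing_rate)
    if (nm > 0) G[sample(zero, nm)] <- NA_integer_
  }

  # per-sample planted qualifying burden (rare variants in the planted mask)
  burden <- rep(0, n)
  planted_carrier <- rep(FALSE, n)
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      jj <- which(gene_of == planted$gene[i] &
                    vapply(terms, assign_mask, character(1), masks = masks) ==
                      planted$mask[i] & !is_common)
      if (!length(jj)) next
      sub <- G[, jj, drop = FALSE]; sub[is.na(sub)] <- 0L
      b <- rowSums(sub)
      burden <- burden + planted$beta[i] * b
      planted_carrier <- planted_carrier | b > 0
    }
  }
  list(G = G,
       annotations = data.frame(variant_id = variant_ids, gene = gene_of,
                                consequence_terms = all_terms,
                                stringsAsFactors = FALSE),
       meta = data.frame(variant_id = variant_ids, chrom = chrom, pos = pos,
                         intent = intent, common = is_common,
                         stringsAsFactors = FALSE),
       planted_burden = burden, planted_carrier = planted_carrier)
}

sim_phenotypes <- function(config, anc, sample_ids, geno) {
  n <- length(anc)
  alpha <- stats::qlogis(pmin(pmax(config$case_fraction_per_ancestry, 1e-6),
                              1 - 1e-6))
  eta <- alpha[anc] + geno$planted_burden
  case <- stats::rbinom(n, 1L, stats::plogis(eta))
  status <- case
  noncase <- which(case == 0L)
  p_ctrl <- config$control_fraction_per_ancestry /
    pmax(1e-9, 1 - config$case_fraction_per_ancestry)
  is_ctrl <- stats::rbinom(length(noncase), 1L,
                           pmin(1, p_ctrl[anc[noncase]]))
  status[noncase][is_ctrl == 0L] <- NA_integer_

  k_pc <- 20L
  pc_means <- matrix(stats::rnorm(length(config$n_per_ancestry) * k_pc, 0, 2),
                     nrow = length(config$n_per_ancestry),
                     dimnames = list(names(config$n_per_ancestry), NULL))
  pcs <- pc_means[anc, , drop = FALSE] +
    matrix(stats::rnorm(n * k_pc), n, k_pc)
  colnames(pcs) <- paste0("PC", seq_len(k_pc))
  samples <- data.frame(
    sample_id = sample_ids, ancestry = anc, status = status,
    age = round(stats::rnorm(n, 75, 8), 1),
    sex = stats::rbinom(n, 1L, 0.55),
    platform = stats::rbinom(n, 1L, 0.5),
    pcr = stats::rbinom(n, 1L, 0.4),
    stringsAsFactors = FALSE)
  list(samples = cbind(samples, as.data.frame(pcs)), status = status)
}

sim_traits <- function(config, status, planted_carrier) {
  specs <- config$trait_specs
  n <- length(status)
  case <- !is.na(status) & status == 1
  out <- list(AD = status)
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    if (s$kind == "binary") {
      p <- stats::plogis(stats::qlogis(s$baseline) +
                           s$case_shift * case +
                           s$carrier_shift * planted_carrier)
      v <- stats::rbinom(n, 1L, p)
    } else {
      latent <- s$baseline + s$case_shift * case +
        s$carrier_shift * planted_carrier + stats::rnorm(n, 0, s$sd)
      v <- if (s$kind == "ordinal") {
        pmin(pmax(round(latent), 0), 6)
      } else round(latent, 3)
    }
    v[stats::runif(n) < config$trait_missing_rate] <- NA
    out[[s$name]] <- v
  }
  as.data.frame(out)
}

sim_ages <- function(config, geno) {
  m <- nrow(geno$annotations)
  sub <- geno$G; sub[is.na(sub)] <- 0L
  af <- colSums(sub) / (2 * nrow(sub))
  age <- stats::rlnorm(m, meanlog = log(pmax(8, 4e4 * af)), sdlog = 0.9)
  spread <- exp(abs(stats::rnorm(m, 0, 0.6)) + 0.05)
  group <- rep("background", m)
  if (!is.null(config$planted_genes)) {
    lab <- ifelse(config$planted_genes$beta > 0, "risk", "protective")
    idx <- match(geno$annotations$gene, config$planted_genes$gene)
    group[!is.na(idx)] <- lab[idx[!is.na(idx)]]
  }
  data.frame(variant_id = geno$annotations$variant_id, group = group,
             age = round(age, 2), lower = round(age / spread, 2),
             upper = round(age * spread, 2), stringsAsFactors = FALSE)
}

#' Cohort composition summary
#'
#' Case and control fractions, the AD/control ratio and ancestry shares of a
#' sample table (columns \code{status} in \{1, 0, NA\} and \code{ancestry}).
#'
#' @param samples data.frame with status and ancestry columns.
#' @return List: n, n_case, n_control, case_fraction, control_fraction,
#'   ad_control_ratio, ancestry_shares (named vector).
#' @export
cohort_summary <- function(samples) {
  n <- nrow(samples)
  n_case <- sum(samples$status == 1, na.rm = TRUE)
  n_control <- sum(samples$status == 0, na.rm = TRUE)
  shares <- sort(table(samples$ancestry) / n, decreasing = TRUE)
  list(n = n, n_case = n_case, n_control = n_control,
       case_fraction = n_case / n, control_fraction = n_control / n,
       ad_control_ratio = n_case / n_control,
       ancestry_shares = stats::setNames(as.numeric(shares), names(shares)))
}
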