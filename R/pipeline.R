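#' Assemble a pipeline configuration
#'
#' Either simulate a cohort (\code{mode = "simulate"}, using
#' \code{cohort} = a [cohort_config()]) or read one from disk
#' (\code{mode = "files"}, using \code{input_dir} as written by
#' [write_cohort()]).
#'
#' @param mode "simulate" or "files".
#' @param cohort A \code{cohort_config} (simulate mode).
#' @param input_dir Cohort directory (files mode).
#' @param maf_threshold Strict MAF bound for qualifying variants.
#' @param tests Gene-based tests to run.
#' @param alpha Family-wise error rate for the significance threshold.
#' @param n_genes_for_threshold Bonferroni denominator override; default the
#'   number of genes actually tested.
#' @param min_carriers Carrier-profile minimum (default 2).
#' @param dominance_threshold Single-ancestry-like cutoff.
#' @param max_ci_ratio,max_age Allele-age quality filters.
#' @param seed Seed used in simulate mode (overrides the cohort config seed).
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(mode = c("simulate", "files"),
                            cohort = cohort_config(),
                            input_dir = NULL,
                            maf_threshold = 0.01,
                            tests = c("burden", "skat", "skato", "acatv", "acato"),
                            alpha = 0.05,
                            n_genes_for_threshold = NULL,
                            min_carriers = 2,
                            dominance_threshold = 0.75,
                            max_ci_ratio = 10,
                            max_age = 500000,
                            seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "files") {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stop("files mode requires an existing input_dir")
    }
  } else if (!is.null(seed)) {
    cohort$seed <- as.integer(seed)
  }
  stopifnot(maf_threshold > 0, maf_threshold <= 0.5, alpha > 0, alpha < 1)
  structure(list(mode = mode, cohort = cohort, input_dir = input_dir,
                 maf_threshold = maf_threshold, tests = tests, alpha = alpha,
                 n_genes_for_threshold = n_genes_for_threshold,
                 min_carriers = min_carriers,
                 dominance_threshold = dominance_threshold,
                 max_ci_ratio = max_ci_ratio, max_age = max_age),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments; the
#' \code{cohort} block is passed to [cohort_config()] (with
#' \code{planted_genes} as a list of gene/mask/beta records).
#'
#' @param path YAML file.
#' @return \code{pipeline_config}.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort)) {
    args <- y$cohort
    for (nm in c("n_per_ancestry", "case_fraction_per_ancestry",
                 "control_fraction_per_ancestry")) {
      if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
    }
    if (!is.null(args$planted_genes)) {
      args$planted_genes <- do.call(rbind, lapply(args$planted_genes,
                                                  as.data.frame))
    }
    do.call(cohort_config, args)
  } else cohort_config()
  args <- y[setdiff(names(y), "cohort")]
  do.call(pipeline_config, c(list(cohort = cohort), args))
}

#' Run the full rare-variant analysis pipeline
#'
#' Stages, in dependency order: obtain cohort (simulate or read) -> annotate
#' and build (gene, mask) qualifying sets -> fit the AD null model and run the
#' gene-based tests -> significance against the Bonferroni threshold ->
#' carrier odds ratios and trait profiles for significant genes -> ancestry
#' concentration profiles -> allele-age filtering and group comparison. All
#' stage tables are written as TSV under \code{out_dir} together with a JSON
#' manifest (config hash, seed, per-stage row counts). Deterministic given
#' (config, seed).
#'
#' @param config A \code{pipeline_config} or path to a YAML file.
#' @param out_dir Output directory.
#' @return Invisible list with cohort, sets, results, significant, or_table,
#'   trait_cells, profiles, concentration, ages, manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  manifest <- list(seed = if (config$mode == "simulate") config$cohort$seed
                   else NA_integer_,
                   config_hash = config_hash(config), stages = list())
  log_stage <- function(name, ...) {
    counts <- list(...)
    manifest$stages[[name]] <<- counts
    message(sprintf("[%s] %s", name,
                    paste(names(counts), unlist(counts), sep = "=",
                          collapse = " ")))
  }
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  run <- function() {
    stage <<- "cohort"
    cohort <- if (config$mode == "simulate") simulate_cohort(config$cohort)
              else read_cohort(config$input_dir)
    log_stage("cohort", samples = nrow(cohort$samples),
              variants = ncol(cohort$genotypes))

    stage <<- "mask"
    # qualification (MAF, carriers) is computed on the analysis samples,
    # i.e. those with known case/control status
    known <- !is.na(cohort$samples$status)
    G_known <- cohort$genotypes[known, , drop = FALSE]
    annotated <- annotate_variants(cohort$annotations, G_known)
    sets_known <- build_qualifying_sets(annotated, G_known,
                                        maf_threshold = config$maf_threshold)
    n_qual <- sum(vapply(sets_known, function(s) ncol(s$G), integer(1)))
    log_stage("mask", annotated = nrow(annotated), sets = length(sets_known),
              qualifying_variants = n_qual)

    stage <<- "test"
    covars <- as.matrix(cohort$samples[known, c("age", "sex", "platform",
                                                "pcr",
                                                paste0("PC", 1:20))])
    null <- fit_null(cohort$samples$status[known], covars, kind = "binary")
    results <- run_gene_tests(sets_known, null, tests = config$tests)
    write_tsv(results, "results.tsv")
    n_genes <- length(unique(vapply(sets_known, `[[`, character(1), "gene")))
    denom <- if (is.null(config$n_genes_for_threshold)) n_genes
             else config$n_genes_for_threshold
    thr <- bonferroni_threshold(config$alpha, max(1, denom))
    sig_genes <- unique(results$gene[results$p < thr])
    log_stage("test", results = nrow(results), genes_tested = n_genes,
              threshold = thr, significant_genes = length(sig_genes))
    write_tsv(data.frame(gene = sig_genes), "significant_genes.tsv")

    stage <<- "carrier"
    target_sets <- sets_known[vapply(sets_known, function(s)
      s$gene %in% sig_genes, logical(1))]
    or_rows <- list(); cell_rows <- list()
    for (s in target_sets) {
      flags <- carrier_status(s)
      strat <- tryCatch(stratified_or(flags, null$y,
                                      cohort$samples$ancestry[known]),
                        error = function(e) NULL)
      if (!is.null(strat)) {
        ests <- c(strat$per_ancestry, list(pooled = strat$pooled))
        for (nm in names(ests)) {
          e <- ests[[nm]]
          or_rows[[length(or_rows) + 1L]] <- data.frame(
            gene = s$gene, mask = s$mask, stratum = nm, or = e$or,
            ci_lower = e$ci_lower, ci_upper = e$ci_upper,
            corrected = e$corrected)
        }
      }
      cells <- gene_trait_profile(flags, cohort$samples[known, , drop = FALSE],
                                  is_case = null$y,
                                  gene = paste(s$gene, s$mask, sep = ":"))
      if (!is.null(cells)) cell_rows[[length(cell_rows) + 1L]] <- cells
    }
    or_table <- if (length(or_rows)) do.call(rbind, or_rows) else NULL
    trait_cells <- if (length(cell_rows)) do.call(rbind, cell_rows) else NULL
    if (!is.null(or_table)) write_tsv(or_table, "carrier_or.tsv")
    if (!is.null(trait_cells)) write_tsv(trait_cells, "trait_cells.tsv")
    log_stage("carrier", genes = length(target_sets),
              or_rows = NROW(or_table), trait_cells = NROW(trait_cells))

    stage <<- "concentration"
    qual_ids <- unlist(lapply(sets_known, `[[`, "variant_ids"), use.names = FALSE)
    qual_ids <- unique(qual_ids)
    profiles <- build_profiles(
      cohort$genotypes[, qual_ids, drop = FALSE],
      cohort$samples$status, cohort$samples$ancestry,
      min_carriers = config$min_carriers)
    conc <- if (nrow(profiles)) {
      suppressWarnings(compare_concentration(profiles,
                                             config$dominance_threshold))
    } else NULL
    write_tsv(profiles, "profiles.tsv")
    if (!is.null(conc)) write_tsv(conc$two_group, "concentration_summary.tsv")
    log_stage("concentration", profiles = nrow(profiles))

    stage <<- "ages"
    ages_out <- NULL
    if (!is.null(cohort$ages) && nrow(cohort$ages)) {
      filt <- filter_ages(cohort$ages, config$max_ci_ratio, config$max_age)
      rec <- filt$retained
      rec$group2 <- ifelse(rec$variant_id %in% unlist(
        lapply(target_sets, `[[`, "variant_ids")), "prioritized", "background")
      cmp <- local({
        tmp <- rec; tmp$group <- tmp$group2
        if (all(c("prioritized", "background") %in% tmp$group)) {
          compare_age_groups(tmp, "prioritized", "background")
        } else NULL
      })
      write_tsv(rec, "ages_filtered.tsv")
      ages_out <- list(filtered = rec, tally = filt$tally, comparison = cmp)
      log_stage("ages", retained = nrow(rec),
                rejected = sum(filt$tally))
    } else {
      log_stage("ages", retained = 0L, rejected = 0L)
    }

    manifest$row_counts <- list(
      variants_in = ncol(cohort$genotypes), qualifying_variants = n_qual,
      results = nrow(results))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(cohort = cohort, sets = sets_known, results = results,
         significant = sig_genes, threshold = thr, or_table = or_table,
         trait_cells = trait_cells, profiles = profiles, concentration = conc,
         ages = ages_out, manifest = manifest)
  }
  out <- tryCatch(run(), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(out)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config, digits.d = 12)), tmp)
  unname(tools::md5sum(tmp))
}
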