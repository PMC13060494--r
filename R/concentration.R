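#' Enrichment classification thresholds
#'
#' Defaults follow the carrier-count rules: AD-enriched needs >= 2 AD carriers
#' and either no control carriers or an AD/control carrier ratio >= 1; AD-skew
#' needs >= 5 AD carriers and ratio >= 5 (or no control carriers). The >= 1
#' ratio rule is meaningful because it exceeds the cohort's own baseline
#' case/control ratio, which is recomputed from the supplied phenotypes, never
#' hard-coded.
#'
#' @param min_ad_enriched,ratio_enriched,min_ad_skew,ratio_skew Rule cutoffs.
#' @param dominance Dominant-ancestry proportion defining single-ancestry-like
#'   (inclusive, default 0.75).
#' @param baseline_ratio Cohort AD/control ratio (informational).
#' @return List of class \code{enrichment_thresholds}.
#' @export
enrichment_thresholds <- function(min_ad_enriched = 2, ratio_enriched = 1,
                                  min_ad_skew = 5, ratio_skew = 5,
                                  dominance = 0.75, baseline_ratio = NA_real_) {
  stopifnot(min_ad_skew >= min_ad_enriched, ratio_skew >= ratio_enriched,
            dominance > 0, dominance <= 1)
  structure(list(min_ad_enriched = min_ad_enriched,
                 ratio_enriched = ratio_enriched,
                 min_ad_skew = min_ad_skew, ratio_skew = ratio_skew,
                 dominance = dominance, baseline_ratio = baseline_ratio),
            class = "enrichment_thresholds")
}

#' Per-variant carrier profiles split by phenotype and ancestry
#'
#' Carriers are samples with dosage >= 1 (missing = non-carrier). Samples with
#' unknown AD status are excluded from the AD/control counts but still counted
#' in the ancestry composition. Only variants with at least \code{min_carriers}
#' total carriers are profiled.
#'
#' @param G Samples x variants dosage matrix (column names = variant ids).
#' @param is_case Case status per sample (0/1, NA = unknown).
#' @param ancestry Ancestry label per sample.
#' @param min_carriers Minimum total carriers (default 2).
#' @param thresholds An \code{enrichment_thresholds}; baseline ratio is filled
#'   from the phenotypes if missing.
#' @return data.frame: variant_id, n_carriers, ad_carriers, control_carriers,
#'   dominant_ancestry, dominant_proportion, simpson, class
#'   (AD-skew/AD-enriched/other), plus one \code{anc_<label>} count column per
#'   ancestry.
#' @export
build_profiles <- function(G, is_case, ancestry, min_carriers = 2,
                           thresholds = enrichment_thresholds()) {
  G <- as.matrix(G)
  stopifnot(min_carriers >= 1)
  if (nrow(G) != length(is_case) || nrow(G) != length(ancestry)) {
    stop("phenotype/genotype sample mismatch")
  }
  if (is.na(thresholds$baseline_ratio)) {
    thresholds$baseline_ratio <-
      sum(is_case == 1, na.rm = TRUE) / sum(is_case == 0, na.rm = TRUE)
  }
  anc_levels <- sort(unique(as.character(ancestry)))
  carrier <- !is.na(G) & G >= 1
  total <- colSums(carrier)
  keep <- which(total >= min_carriers)
  rows <- lapply(keep, function(j) {
    idx <- carrier[, j]
    counts <- vapply(anc_levels, function(a) sum(idx & ancestry == a),
                     integer(1))
    ad <- sum(idx & !is.na(is_case) & is_case == 1)
    ctrl <- sum(idx & !is.na(is_case) & is_case == 0)
    prop <- counts / sum(counts)
    dom <- dominant_from_counts(counts)
    cls <- classify_counts(ad, ctrl, thresholds)
    c(list(variant_id = colnames(G)[j], n_carriers = sum(idx),
           ad_carriers = ad, control_carriers = ctrl,
           dominant_ancestry = dom$label, dominant_proportion = dom$proportion,
           simpson = 1 - sum(prop^2), class = cls),
      stats::setNames(as.list(counts), paste0("anc_", anc_levels)))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(out)) {
    out <- data.frame(variant_id = character(0), n_carriers = integer(0),
                      ad_carriers = integer(0), control_carriers = integer(0),
                      dominant_ancestry = character(0),
                      dominant_proportion = numeric(0), simpson = numeric(0),
                      class = character(0))
  }
  attr(out, "thresholds") <- thresholds
  out
}

dominant_from_counts <- function(counts) {
  stopifnot(sum(counts) > 0)
  nm <- sort(names(counts))           # lexicographic tie-break
  counts <- counts[nm]
  k <- which.max(counts)              # first maximum after sorting
  list(label = nm[k], proportion = unname(counts[k] / sum(counts)))
}

classify_counts <- function(ad, ctrl, thresholds) {
  skew <- ad >= thresholds$min_ad_skew &&
    (ctrl == 0 || ad / ctrl >= thresholds$ratio_skew)
  enr <- ad >= thresholds$min_ad_enriched &&
    (ctrl == 0 || ad / ctrl >= thresholds$ratio_enriched)
  if (skew) "AD-skew" else if (enr) "AD-enriched" else "other"
}

#' Classify a variant's AD enrichment
#'
#' AD-skew is a subset of AD-enriched by construction; the more specific label
#' is reported.
#'
#' @param profile One-row data.frame (or list) with \code{ad_carriers} and
#'   \code{control_carriers}.
#' @param thresholds An \code{enrichment_thresholds}.
#' @return "AD-skew", "AD-enriched" or "other".
#' @export
#' @examples
#' classify_enrichment(list(ad_carriers = 5, control_carriers = 1))  # AD-skew
classify_enrichment <- function(profile, thresholds = enrichment_thresholds()) {
  classify_counts(profile$ad_carriers, profile$control_carriers, thresholds)
}

#' Dominant ancestry of a variant's carriers
#'
#' @param counts Named vector of per-ancestry carrier counts (total > 0).
#' @return List: label, proportion. Ties break to the lexicographically
#'   smallest label; the proportion is unaffected.
#' @export
#' @examples
#' dominant_ancestry(c(EUR = 3, AFR = 1))  # EUR, 0.75
dominant_ancestry <- function(counts) {
  dominant_from_counts(counts)
}

#' Single-ancestry-like call
#'
#' TRUE iff the dominant-ancestry proportion is at or above the threshold
#' (inclusive).
#'
#' @param profile List/row with \code{dominant_proportion} (or a named count
#'   vector).
#' @param threshold Dominance cutoff, default 0.75.
#' @return Logical.
#' @export
is_single_ancestry_like <- function(profile, threshold = 0.75) {
  prop <- if (is.atomic(profile) && is.numeric(profile)) {
    dominant_from_counts(profile)$proportion
  } else {
    profile$dominant_proportion
  }
  prop >= threshold
}

#' Gini-Simpson diversity of carrier ancestry
#'
#' \eqn{D = 1 - \sum_i p_i^2} over ancestry shares of the variant's carriers;
#' 0 means all carriers share one ancestry, and the maximum \eqn{1 - 1/K} is
#' attained only at the uniform mixture over K ancestries. Lower D = greater
#' ancestry concentration.
#'
#' @param counts Named vector of per-ancestry carrier counts (total > 0).
#' @return D in [0, 1 - 1/K].
#' @export
#' @examples
#' simpson_diversity(c(EUR = 2, AFR = 2))  # 0.5
simpson_diversity <- function(counts) {
  stopifnot(sum(counts) > 0)
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Compare ancestry concentration between enrichment groups
#'
#' Two-group comparison (AD-enriched including AD-skew, versus other) of the
#' dominant-ancestry proportion and the Gini-Simpson diversity: per-group
#' medians, two-sided Wilcoxon rank-sum p-values, and the fraction of each
#' group that is single-ancestry-like. A three-group display summary
#' (AD-skew / AD-enriched / other) is also returned.
#'
#' @param profiles Output of [build_profiles()].
#' @param dominance_threshold Single-ancestry-like cutoff (default 0.75).
#' @return List: two_group (data.frame), p_dominant, p_simpson, three_group.
#' @export
compare_concentration <- function(profiles, dominance_threshold = 0.75) {
  enriched <- profiles$class %in% c("AD-enriched", "AD-skew")
  if (!any(enriched) || all(enriched)) {
    warning("one comparison group is empty; Wilcoxon comparison skipped")
  }
  grp <- ifelse(enriched, "AD-enriched", "other")
  summ <- function(rows) {
    data.frame(
      n = nrow(rows),
      median_dominant = stats::median(rows$dominant_proportion),
      median_simpson = stats::median(rows$simpson),
      frac_single_ancestry_like =
        mean(rows$dominant_proportion >= dominance_threshold))
  }
  two <- do.call(rbind, lapply(split(profiles, grp), summ))
  two <- cbind(group = rownames(two), two, row.names = NULL)
  p_dom <- p_simp <- NA_real_
  if (any(enriched) && !all(enriched)) {
    p_dom <- suppressWarnings(stats::wilcox.test(
      profiles$dominant_proportion[enriched],
      profiles$dominant_proportion[!enriched])$p.value)
    p_simp <- suppressWarnings(stats::wilcox.test(
      profiles$simpson[enriched], profiles$simpson[!enriched])$p.value)
  }
  three <- do.call(rbind, lapply(split(profiles, profiles$class), summ))
  three <- cbind(group = rownames(three), three, row.names = NULL)
  list(two_group = two, p_dominant = p_dom, p_simpson = p_simp,
       three_group = three)
}
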