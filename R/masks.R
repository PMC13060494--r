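#' Annotate variants with most severe consequence, mask and frequencies
#'
#' Joins a raw annotation table to genotype-derived allele statistics. One
#' output row per (variant, gene) annotation; a variant annotated to several
#' genes contributes independently to each.
#'
#' @param annotations data.frame with columns \code{variant_id}, \code{gene},
#'   \code{consequence_terms} (comma-separated SO terms).
#' @param G Samples x variants dosage matrix; column names are variant ids and
#'   must cover every annotated variant.
#' @param masks Mask definitions, see [mask_definitions()].
#' @param order Severity order, see [so_severity_order()].
#' @return data.frame with columns variant_id, gene, consequence_terms,
#'   most_severe, mask, ac, an, af, maf.
#' @export
annotate_variants <- function(annotations, G,
                              masks = mask_definitions(),
                              order = so_severity_order()) {
  need <- c("variant_id", "gene", "consequence_terms")
  if (!all(need %in% names(annotations))) {
    stop("annotations must have columns: ", paste(need, collapse = ", "))
  }
  miss <- setdiff(annotations$variant_id, colnames(G))
  if (length(miss)) {
    stop("variants missing from genotype matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  stats <- allele_stats(G)
  terms <- strsplit(as.character(annotations$consequence_terms), ",[ ]*")
  ms <- vapply(terms, most_severe, character(1), order = order)
  out <- data.frame(
    variant_id = annotations$variant_id,
    gene = annotations$gene,
    consequence_terms = annotations$consequence_terms,
    most_severe = ms,
    mask = vapply(ms, assign_mask, character(1), masks = masks),
    stringsAsFactors = FALSE
  )
  cbind(out, stats[out$variant_id, , drop = FALSE], row.names = NULL)
}

#' Build qualifying variant sets per (gene, mask)
#'
#' A variant enters the set for (gene, mask) iff it is annotated to that gene,
#' its most severe consequence falls in that mask, its minor allele frequency
#' on the analysis samples is strictly below \code{maf_threshold}, and it has
#' at least one called carrier. Empty sets are absent from the result.
#'
#' Weights default to the Beta(1, 25) density evaluated at the MAF, the
#' standard rare-variant up-weighting.
#'
#' @param annotated Output of [annotate_variants()] (or equivalent).
#' @param G Samples x variants dosage matrix.
#' @param maf_threshold Strict MAF upper bound, in (0, 0.5]; default 0.01.
#' @param weight_fun Function MAF -> positive weight.
#' @return Named list (\code{"gene:mask"}) of \code{qv_set} objects with
#'   fields gene, mask, G (samples x qualifying variants), maf, weights,
#'   variant_ids.
#' @export
build_qualifying_sets <- function(annotated, G, maf_threshold = 0.01,
                                  weight_fun = function(maf) stats::dbeta(maf, 1, 25)) {
  stopifnot(maf_threshold > 0, maf_threshold <= 0.5)
  if (!all(annotated$variant_id %in% colnames(G))) {
    stop("genotype matrix does not cover all annotated variants")
  }
  keep <- annotated$mask != "none" &
    !is.na(annotated$maf) & annotated$maf < maf_threshold &
    annotated$ac > 0
  ann <- annotated[keep, , drop = FALSE]
  if (nrow(ann) == 0L) return(structure(list(), names = character(0)))
  key <- paste(ann$gene, ann$mask, sep = ":")
  sets <- lapply(split(seq_len(nrow(ann)), key), function(idx) {
    a <- ann[idx, , drop = FALSE]
    sub <- G[, a$variant_id, drop = FALSE]
    new_qv_set(gene = a$gene[[1]], mask = a$mask[[1]], G = sub,
               maf = a$maf, weights = weight_fun(a$maf),
               variant_ids = a$variant_id)
  })
  sets[order(names(sets))]
}

new_qv_set <- function(gene, mask, G, maf, weights, variant_ids) {
  stopifnot(ncol(G) == length(maf), length(maf) == length(weights),
            all(weights > 0))
  structure(
    list(gene = gene, mask = mask, G = G, maf = maf, weights = weights,
         variant_ids = variant_ids),
    class = "qv_set"
  )
}

#' @export
print.qv_set <- function(x, ...) {
  cat(sprintf("<qv_set> gene %s, mask %s: %d variant(s), %d sample(s)\n",
              x$gene, x$mask, ncol(x$G), nrow(x$G)))
  invisible(x)
}
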