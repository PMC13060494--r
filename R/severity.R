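#' Sequence Ontology consequence severity order
#'
#' Returns the ordered vocabulary of Sequence Ontology (SO) consequence terms
#' used to pick the single most severe consequence of a variant, rank 1 being
#' the most severe (\code{transcript_ablation}) and the last rank the least
#' (\code{intergenic_variant}). This is the VEP-style selection order used by
#' large sequencing consortia; note that \code{splice_region_variant} ranks
#' above \code{splice_donor_5th_base_variant} in this ordering.
#'
#' @return Character vector of 39 SO terms, most severe first.
#' @export
#' @examples
#' head(so_severity_order(), 4)
so_severity_order <- function() {
  c(
    "transcript_ablation",
    "splice_acceptor_variant",
    "splice_donor_variant",
    "stop_gained",
    "frameshift_variant",
    "stop_lost",
    "start_lost",
    "transcript_amplification",
    "inframe_insertion",
    "inframe_deletion",
    "missense_variant",
    "protein_altering_variant",
    "splice_region_variant",
    "splice_donor_5th_base_variant",
    "splice_donor_region_variant",
    "splice_polypyrimidine_tract_variant",
    "incomplete_terminal_codon_variant",
    "stop_retained_variant",
    "synonymous_variant",
    "start_retained_variant",
    "coding_sequence_variant",
    "mature_miRNA_variant",
    "5_prime_UTR_variant",
    "3_prime_UTR_variant",
    "non_coding_transcript_exon_variant",
    "intron_variant",
    "NMD_transcript_variant",
    "non_coding_transcript_variant",
    "upstream_gene_variant",
    "downstream_gene_variant",
    "TFBS_ablation",
    "TFBS_amplification",
    "TF_binding_site_variant",
    "regulatory_region_ablation",
    "regulatory_region_amplification",
    "feature_elongation",
    "regulatory_region_variant",
    "feature_truncation",
    "intergenic_variant"
  )
}

#' Annotation mask definitions
#'
#' The three annotation-defined variant classes used for gene-based testing:
#' \describe{
#'   \item{M1}{loss-of-function-like: transcript_ablation, stop_gained,
#'     frameshift_variant, stop_lost, start_lost, transcript_amplification}
#'   \item{M2}{protein-altering: inframe_insertion, inframe_deletion,
#'     missense_variant, protein_altering_variant}
#'   \item{M3}{splice-region: splice_acceptor_variant, splice_donor_variant,
#'     splice_donor_5th_base_variant, splice_region_variant,
#'     splice_donor_region_variant, splice_polypyrimidine_tract_variant}
#' }
#' The member sets are pairwise disjoint. \code{include_amplification = FALSE}
#' drops \code{transcript_amplification} from M1 (an alternative published
#' variant of the M1 list).
#'
#' @param include_amplification Keep transcript_amplification in M1 (default
#'   TRUE).
#' @return Named list of character vectors \code{M1}, \code{M2}, \code{M3}.
#' @export
mask_definitions <- function(include_amplification = TRUE) {
  m1 <- c("transcript_ablation", "stop_gained", "frameshift_variant",
          "stop_lost", "start_lost", "transcript_amplification")
  if (!include_amplification) m1 <- setdiff(m1, "transcript_amplification")
  list(
    M1 = m1,
    M2 = c("inframe_insertion", "inframe_deletion", "missense_variant",
           "protein_altering_variant"),
    M3 = c("splice_acceptor_variant", "splice_donor_variant",
           "splice_donor_5th_base_variant", "splice_region_variant",
           "splice_donor_region_variant", "splice_polypyrimidine_tract_variant")
  )
}

#' Most severe consequence term
#'
#' Picks, from a set of SO terms annotated to one variant, the term with the
#' smallest severity rank. Invariant to the input ordering.
#'
#' @param terms Character vector of SO terms (non-empty).
#' @param order Severity order, most severe first; defaults to
#'   [so_severity_order()].
#' @return Single SO term.
#' @export
#' @examples
#' most_severe(c("missense_variant", "stop_gained"))  # "stop_gained"
most_severe <- function(terms, order = so_severity_order()) {
  if (length(terms) == 0L) stop("`terms` must be non-empty")
  ranks <- match(terms, order)
  if (anyNA(ranks)) {
    stop("unknown consequence term(s): ",
         paste(unique(terms[is.na(ranks)]), collapse = ", "))
  }
  order[min(ranks)]
}

#' Assign a consequence term to an annotation mask
#'
#' Total function over the severity vocabulary: returns the id of the unique
#' mask whose member set contains \code{term}, or \code{"none"}.
#'
#' @param term Single SO term.
#' @param masks Mask definitions as from [mask_definitions()].
#' @return \code{"M1"}, \code{"M2"}, \code{"M3"} or \code{"none"}.
#' @export
#' @examples
#' assign_mask("missense_variant")    # "M2"
#' assign_mask("synonymous_variant")  # "none"
assign_mask <- function(term, masks = mask_definitions()) {
  stopifnot(length(term) == 1L)
  for (id in names(masks)) {
    if (term %in% masks[[id]]) return(id)
  }
  "none"
}
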