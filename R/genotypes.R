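#' Decompose a multi-allelic VCF record into bi-allelic records
#'
#' A record is a list with fields \code{chrom}, \code{pos}, \code{id},
#' \code{ref}, \code{alt} (character vector, one element per alternate allele)
#' and \code{gt} (character vector of per-sample GT strings such as
#' \code{"0/1"}, \code{"1|2"}, \code{"./."}). One bi-allelic record is
#' returned per alternate allele; the per-sample dosage of each output record
#' counts that allele's occurrences in the original genotype, so total
#' alternate dosage per sample is conserved across outputs. Genotypes carrying
#' a different alternate allele become reference calls in the record for this
#' allele (dosage contribution 0). Fully missing genotypes stay missing.
#'
#' @param record VCF-like record (see Details).
#' @return List of bi-allelic records, each gaining a \code{dosage} integer
#'   vector (NA = missing) and an \code{allele_index} field.
#' @export
decompose_multiallelic <- function(record) {
  stopifnot(is.list(record), length(record$alt) >= 1L)
  alleles <- parse_gt(record$gt, n_alt = length(record$alt))
  lapply(seq_along(record$alt), function(k) {
    dos <- colSums(alleles == k)
    dos[colSums(is.na(alleles)) == nrow(alleles)] <- NA_integer_
    gt <- gt_from_dosage(dos)
    list(chrom = record$chrom, pos = record$pos,
         id = if (length(record$alt) == 1L) record$id
              else paste0(record$id, "_", k),
         ref = record$ref, alt = record$alt[[k]],
         allele_index = k, dosage = as.integer(dos), gt = gt)
  })
}

# Parse GT strings into a 2 x n_samples matrix of allele codes (NA = missing).
# Haploid calls are accepted and padded with NA in the second row.
parse_gt <- function(gt, n_alt = 1L) {
  out <- matrix(NA_integer_, nrow = 2L, ncol = length(gt))
  pieces <- strsplit(gt, "[/|]")
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    if (length(p) < 1L || length(p) > 2L) {
      stop(sprintf("malformed genotype '%s' for sample index %d",
                   gt[[i]], i), call. = FALSE)
    }
    v <- suppressWarnings(ifelse(p == ".", NA_integer_, as.integer(p)))
    if (any(!is.na(v) & (v < 0L | v > n_alt)) ||
        any(is.na(v) & p != ".")) {
      stop(sprintf("malformed genotype '%s' for sample index %d",
                   gt[[i]], i), call. = FALSE)
    }
    out[seq_along(v), i] <- v
  }
  out
}

gt_from_dosage <- function(dos) {
  gt <- rep("./.", length(dos))
  gt[!is.na(dos) & dos == 0] <- "0/0"
  gt[!is.na(dos) & dos == 1] <- "0/1"
  gt[!is.na(dos) & dos == 2] <- "1/1"
  gt
}

#' Allele counts and minor allele frequency from a dosage matrix
#'
#' Missing genotypes are excluded from both numerator and denominator. Allele
#' frequencies above 0.5 are folded (\code{maf = min(af, 1 - af)}).
#'
#' @param G Samples x variants dosage matrix over \{0, 1, 2, NA\}.
#' @return data.frame with columns \code{ac} (alternate allele count),
#'   \code{an} (called allele number), \code{af}, \code{maf}.
#' @export
allele_stats <- function(G) {
  G <- as.matrix(G)
  ac <- colSums(G, na.rm = TRUE)
  an <- 2L * colSums(!is.na(G))
  af <- ifelse(an > 0, ac / an, NA_real_)
  data.frame(ac = ac, an = an, af = af,
             maf = pmin(af, 1 - af), row.names = colnames(G))
}
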