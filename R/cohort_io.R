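#' Write a cohort to disk
#'
#' Emits \code{genotypes.vcf} (VCF 4.2, GT-only, one bi-allelic record per
#' variant, 1-based positions), \code{annotations.tsv},
#' \code{phenotypes.tsv} and \code{ages.tsv}. Output is byte-deterministic
#' given the cohort (no timestamps). A [read_cohort()] round trip reproduces
#' the dosage matrix exactly (missing genotypes are encoded "./.").
#'
#' @param cohort A \code{radvar_cohort}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "radvar_cohort"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", dir)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             annotations = file.path(dir, "annotations.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             ages = file.path(dir, "ages.tsv"))

  G <- cohort$genotypes
  meta <- cohort$variant_meta
  if (is.null(meta)) {
    meta <- data.frame(variant_id = colnames(G),
                       chrom = 1L, pos = seq_len(ncol(G)) * 100L)
  }
  bases <- c("A", "C", "G", "T")
  ref <- bases[1L + (seq_len(ncol(G)) - 1L) %% 4L]
  alt <- bases[1L + seq_len(ncol(G)) %% 4L]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=radvar_synthetic_cohort",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           sprintf("##contig=<ID=%s>", unique(meta$chrom)),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  gt <- apply(G, 2, gt_from_dosage)          # samples x variants
  body <- vapply(seq_len(ncol(G)), function(j) {
    paste(c(meta$chrom[j], meta$pos[j], colnames(G)[j], ref[j], alt[j],
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), paths[["vcf"]])

  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  write_tsv(cohort$annotations, paths[["annotations"]])
  write_tsv(cohort$samples, paths[["phenotypes"]])
  write_tsv(cohort$ages, paths[["ages"]])
  invisible(paths)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' The VCF is parsed with \pkg{VariantAnnotation}; GT strings are converted to
#' a samples x variants dosage matrix ("./." becomes NA). Any conforming
#' source works, not just [write_cohort()] output.
#'
#' @param dir Directory with genotypes.vcf, annotations.tsv, phenotypes.tsv
#'   and (optionally) ages.tsv.
#' @return List of class \code{radvar_cohort}.
#' @export
read_cohort <- function(dir) {
  vcf_path <- file.path(dir, "genotypes.vcf")
  if (!file.exists(vcf_path)) stop("missing genotypes.vcf in ", dir)
  G <- read_vcf_dosages(vcf_path)
  ages_path <- file.path(dir, "ages.tsv")
  structure(list(
    samples = utils::read.delim(file.path(dir, "phenotypes.tsv"),
                                stringsAsFactors = FALSE),
    genotypes = G,
    annotations = utils::read.delim(file.path(dir, "annotations.tsv"),
                                    stringsAsFactors = FALSE),
    ages = if (file.exists(ages_path))
      utils::read.delim(ages_path, stringsAsFactors = FALSE) else NULL,
    config = NULL), class = "radvar_cohort")
}

#' Read GT dosages from a VCF file
#'
#' @param path VCF path (plain or bgzipped).
#' @return Samples x variants integer matrix (NA = missing), columns named by
#'   variant id.
#' @export
read_vcf_dosages <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT      # variants x samples
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  counts <- vapply(strsplit(gt, "[/|]"), function(p) {
    if (all(p == ".")) NA_integer_ else sum(p != "." & p != "0")
  }, integer(1))
  dos[] <- counts
  t(dos)
}
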