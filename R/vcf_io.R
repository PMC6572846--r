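#' Write a haploid haplotype matrix as VCF 4.2
#'
#' Sites are written as biallelic records on a single contig named `Y`,
#' with synthetic 1-based positions `1 .. n_snps` (column order), REF `A`
#' and ALT `T`, and haploid GT fields (`0` or `1`, no phase separator).
#' Ancestral alleles are coded 0 and derived alleles 1.
#'
#' @param mat haplotype matrix (samples x sites, values 0/1) as produced by
#'   [drop_mutations()] or [generate_clade_haplotypes()].
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_haplotypes_vcf <- function(mat, path) {
  stopifnot(is.matrix(mat))
  if (!all(mat %in% c(0L, 1L))) stop("matrix must be biallelic 0/1 haploid")
  samples <- rownames(mat)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(mat)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ydemos",
    "##contig=<ID=Y>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt <- t(mat)  # sites x samples
  body <- paste(
    "Y", seq_len(ncol(mat)), colnames(mat) %||% ".", "A", "T", ".", ".",
    ".", "GT",
    do.call(paste, c(split(gt, col(gt)), list(sep = "\t"))),
    sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a haploid haplotype matrix from VCF
#'
#' Parses a VCF (via the `vcfR` reader) and returns the haploid 0/1
#' genotype matrix.  Records with a diploid genotype (containing `/` or
#' `|`) or more than one ALT allele are rejected with an error naming the
#' offending record.
#'
#' @param path VCF file path.
#' @return integer haplotype matrix, samples x sites, preserving the file's
#'   sample and site order; sites named by their ID (or `CHROM:POS` when
#'   the ID is missing).
#' @export
read_haplotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))  # single-record files drop to a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no records")
  rec <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop("multi-allelic record not supported: ", rec[which(multi)[1L]])
  gt <- vcfR::extract.gt(v)
  diploid <- matrix(grepl("[/|]", gt), nrow = nrow(gt),
                    dimnames = dimnames(gt))
  if (any(diploid)) {
    bad <- which(diploid, arr.ind = TRUE)[1L, ]
    stop("diploid genotype in record ", rec[bad[1L]],
         " (sample ", colnames(gt)[bad[2L]], "); haploid GT required")
  }
  if (!all(gt %in% c("0", "1")))
    stop("genotypes must be haploid 0 or 1")
  mat <- t(matrix(as.integer(gt), nrow = nrow(gt),
                  dimnames = dimnames(gt)))
  ids <- fix[, "ID"]
  colnames(mat) <- ifelse(is.na(ids) | ids == ".", rec, ids)
  mat
}
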