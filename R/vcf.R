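#' Read founder haplotypes from a VCF of F1 cross genotypes
#'
#' Founder haplotypes are derived experimentally by crossing one male of an
#' isofemale line to a virgin female of the inbred reference strain; each VCF
#' sample is one F1 individual carrying the focal haplotype over a reference
#' chromosome. The focal haplotype's allele at a site is therefore the
#' non-reference allele of a heterozygous call (`0/1 -> 1`), while
#' homozygous-reference calls map to 0. Missing genotypes stay missing
#' (`NA`), they are never coerced to 0. Multi-allelic and non-SNP records in
#' the window are skipped with a warning.
#'
#' A per-haplotype heterozygosity fraction is recorded; haplotypes whose
#' calls are homozygous at every site indicate a failed cross and are flagged
#' downstream by [exclude_failed_and_recombinant()].
#'
#' @param path Path to a VCF 4.x file (plain text or gzipped).
#' @param chrom Chromosome of the extraction window.
#' @param start,end 1-based inclusive window bounds.
#' @param L Window length in bp used for diversity normalization; defaults to
#'   `end - start + 1`.
#' @return A [haplotype_matrix()] with `het_fraction` filled in.
#' @export
read_haplotype_vcf <- function(path, chrom, start, end,
                               L = end - start + 1) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  pos <- as.integer(fix[, "POS"])
  in_win <- fix[, "CHROM"] == chrom & pos >= start & pos <= end
  if (!any(in_win)) {
    stopf("no variant records in window %s:%d-%d", chrom, start, end)
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  snp <- !multi & nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    toupper(fix[, "REF"]) %in% ACGT & toupper(fix[, "ALT"]) %in% ACGT
  n_skip <- sum(in_win & !snp)
  if (n_skip > 0) {
    warnf("skipping %d multi-allelic or non-SNP records in window", n_skip)
  }
  keep <- in_win & snp
  if (!any(keep)) {
    stopf("no biallelic SNP records in window %s:%d-%d", chrom, start, end)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  g <- gsub("|", "/", gt, fixed = TRUE)
  g[is.na(g)] <- "./."
  al <- matrix(NA_integer_, nrow = nrow(g), ncol = ncol(g))
  al[g == "0/0"] <- 0L
  het <- g == "0/1" | g == "1/0"
  al[het] <- 1L
  al[g == "1/1"] <- 1L
  ncall <- colSums(!is.na(al))
  hf <- ifelse(ncall > 0, colSums(het) / ncall, NA_real_)
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = pos[keep],
                      ref = toupper(fix[keep, "REF"]),
                      alt = toupper(fix[keep, "ALT"]),
                      stringsAsFactors = FALSE)
  haplotype_matrix(sites, t(al), ids = colnames(gt), L = L,
                   het_fraction = unname(hf))
}

#' Write founder haplotypes as an F1-cross VCF
#'
#' Inverse of [read_haplotype_vcf()]: each haplotype becomes one VCF sample
#' whose genotype is heterozygous (`0/1`) where the haplotype carries the
#' alternative allele and `0/0` where it carries the reference, as produced
#' by a line x reference-strain cross. Haplotypes flagged as failed crosses
#' (`het_fraction == 0`) are written with homozygous calls (`1/1`/`0/0`).
#' Missing alleles become `./.`.
#'
#' @param x A `HaplotypeMatrix`.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_founder_vcf <- function(x, path) {
  hom <- if (is.null(x$het_fraction)) rep(FALSE, length(x$ids)) else
    !is.na(x$het_fraction) & x$het_fraction == 0
  gt_cols <- vapply(seq_along(x$ids), function(j) {
    al <- x$alleles[j, ]
    one <- if (hom[j]) "1/1" else "0/1"
    ifelse(is.na(al), "./.", ifelse(al == 1L, one, "0/0"))
  }, character(nrow(x$sites)))
  if (nrow(x$sites) == 1L) gt_cols <- matrix(gt_cols, nrow = 1)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(x$sites$chrom)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", x$ids), collapse = "\t"))
  body <- do.call(paste, c(list(x$sites$chrom, x$sites$pos, ".",
                                x$sites$ref, x$sites$alt, ".", "PASS", ".",
                                "GT"),
                           lapply(seq_along(x$ids), function(j) gt_cols[, j]),
                           sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
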