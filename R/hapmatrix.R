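#' Founder haplotype matrix
#'
#' A `HaplotypeMatrix` stores biallelic alleles (0 = reference,
#' 1 = alternative, `NA` = missing) for founder-derived haplotypes at SNPs in
#' a genomic window, plus the window length `L` (bp) used to normalize
#' nucleotide diversity.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`, in any
#'   order (rows are sorted by position).
#' @param alleles Matrix, one row per haplotype, one column per site, entries
#'   in `{0, 1, NA}`.
#' @param ids Haplotype identifiers (default: rownames of `alleles`).
#' @param L Total number of nucleotides examined (bp), the denominator of
#'   per-site nucleotide diversity.
#' @param het_fraction Optional per-haplotype fraction of heterozygous source
#'   genotype calls (see [read_haplotype_vcf()]); a value of 0 marks a failed
#'   cross.
#' @return An object of class `HaplotypeMatrix` with elements `sites`, `ids`,
#'   `alleles`, `L`, `het_fraction`.
#' @export
haplotype_matrix <- function(sites, alleles, ids = rownames(alleles), L,
                             het_fraction = NULL) {
  sites <- as.data.frame(sites)
  check_sites(sites)
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != nrow(sites)) {
    stopf("alleles has %d columns but %d sites given", ncol(alleles),
          nrow(sites))
  }
  if (!all(alleles %in% c(0L, 1L, NA))) {
    stopf("allele matrix entries must be 0, 1 or NA")
  }
  storage.mode(alleles) <- "integer"
  if (is.null(ids)) ids <- paste0("hap", seq_len(nrow(alleles)))
  if (length(ids) != nrow(alleles)) stopf("one id per haplotype required")
  if (!is.numeric(L) || length(L) != 1 || L <= 0) stopf("L must be > 0 bp")
  if (!is.null(het_fraction) && length(het_fraction) != nrow(alleles)) {
    stopf("het_fraction must have one entry per haplotype")
  }
  ord <- site_order(sites)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  alleles <- alleles[, ord, drop = FALSE]
  rownames(alleles) <- ids
  structure(list(sites = sites, ids = as.character(ids), alleles = alleles,
                 L = as.numeric(L), het_fraction = het_fraction),
            class = "HaplotypeMatrix")
}

#' @export
print.HaplotypeMatrix <- function(x, ...) {
  cat(sprintf("HaplotypeMatrix: %d haplotypes x %d sites (L = %g bp)\n",
              nrow(x$alleles), ncol(x$alleles), x$L))
  cat(sprintf("  window %s:%d-%d; %d missing calls\n",
              x$sites$chrom[1], min(x$sites$pos), max(x$sites$pos),
              sum(is.na(x$alleles))))
  invisible(x)
}

#' Subset a haplotype matrix by haplotype
#'
#' @param x A `HaplotypeMatrix`.
#' @param haps Index or id vector of haplotypes to keep.
#' @return A `HaplotypeMatrix`.
#' @export
hap_subset <- function(x, haps) {
  if (is.character(haps)) haps <- match(haps, x$ids)
  haplotype_matrix(x$sites, x$alleles[haps, , drop = FALSE],
                   ids = x$ids[haps], L = x$L,
                   het_fraction = x$het_fraction[haps])
}
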