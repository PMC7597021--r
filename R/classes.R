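#' Pairwise allele differences between haplotypes
#'
#' Counts, for every haplotype pair, the number of sites at which both calls
#' are non-missing and differ, and the number of jointly non-missing sites.
#' Pairwise comparisons involving a missing entry are skipped.
#'
#' @param x A `HaplotypeMatrix`.
#' @return List with matrices `d` (differing sites) and `n` (comparable
#'   sites), both `n_hap x n_hap`.
#' @export
pairwise_differences <- function(x) {
  a <- x$alleles
  obs <- !is.na(a)
  a1 <- a
  a1[!obs] <- 0L
  a0 <- (1L - a)
  a0[!obs] <- 0L
  d <- tcrossprod(a1, a0) + tcrossprod(a0, a1)
  n <- tcrossprod(obs * 1L)
  dimnames(d) <- dimnames(n) <- list(x$ids, x$ids)
  list(d = d, n = n)
}

# fraction of differing non-missing sites, as a dist object
hap_divergence <- function(x) {
  pd <- pairwise_differences(x)
  frac <- pd$d / pd$n
  frac[pd$n == 0] <- NA_real_
  stats::as.dist(frac)
}

# group haplotypes into k groups on the divergence fraction. Two-medoid
# partitioning (PAM) is used for the split: with one tight, abundant class
# and one small, diverse class, cutting an average-linkage dendrogram can
# strand a single diverse haplotype as its own top-level group, whereas
# medoid assignment places every haplotype with its nearest class core. The
# average-linkage tree is still returned for inspection.
cluster_haplotypes <- function(x, k = 2L) {
  if (nrow(x$alleles) < k) stopf("need at least %d haplotypes to cluster", k)
  dv <- hap_divergence(x)
  hc <- stats::hclust(dv, method = "average")
  g <- cluster::pam(dv, k = k, diss = TRUE, cluster.only = TRUE)
  list(tree = hc, groups = g)
}

#' Nucleotide diversity within a set of haplotypes
#'
#' Computes the average number of pairwise nucleotide differences per site,
#' `pi = (sum over pairs d_ij / (n(n-1)/2)) / L`, where `d_ij` is the number
#' of sites differing between haplotypes i and j and `L` is the total number
#' of nucleotides examined (default: the `L` stored in the matrix, e.g. the
#' 36,265 bp of the *Ace* gene). Pairwise comparisons at sites with a missing
#' call in either haplotype are skipped.
#'
#' @param x A `HaplotypeMatrix`, typically restricted to one haplotype class
#'   via [hap_subset()].
#' @param L Number of nucleotides examined (bp).
#' @param class_label Optional label carried into the result.
#' @return A `DiversityResult`: list with `class_label`, `n`, `pi`, `L`.
#' @export
nucleotide_diversity <- function(x, L = x$L, class_label = NA_character_) {
  n <- nrow(x$alleles)
  if (n < 2) stopf("nucleotide diversity is undefined for n < 2 sequences")
  if (!is.numeric(L) || L <= 0) stopf("L must be > 0 bp")
  d <- pairwise_differences(x)$d
  npairs <- n * (n - 1) / 2
  pi <- (sum(d[upper.tri(d)]) / npairs) / L
  structure(list(class_label = class_label, n = n, pi = pi, L = L),
            class = "DiversityResult")
}

#' @export
print.DiversityResult <- function(x, ...) {
  cat(sprintf("pi = %.6g (class %s, n = %d sequences, L = %g bp)\n",
              x$pi, x$class_label, x$n, x$L))
  invisible(x)
}

#' Per-class nucleotide diversity table
#'
#' @param x A `HaplotypeMatrix`.
#' @param assignment A `ClassAssignment` (see [assign_classes()]).
#' @param L Number of nucleotides examined (bp).
#' @param combine_class1 Also report classes 1a + 1b combined as class "1".
#' @return data.frame with columns `class`, `n`, `pi`, `L`.
#' @export
class_diversity <- function(x, assignment, L = x$L, combine_class1 = TRUE) {
  lab <- assignment$label[match(x$ids, assignment$haplotype_id)]
  groups <- split(x$ids, lab)
  groups <- groups[names(groups) %in% c("1a", "1b", "2")]
  if (combine_class1 && all(c("1a", "1b") %in% names(groups))) {
    groups <- c(groups, list(`1` = c(groups[["1a"]], groups[["1b"]])))
  }
  res <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    if (length(ids) < 2) {
      return(data.frame(class = g, n = length(ids), pi = NA_real_, L = L))
    }
    dv <- nucleotide_diversity(hap_subset(x, ids), L = L, class_label = g)
    data.frame(class = g, n = dv$n, pi = dv$pi, L = L)
  })
  out <- do.call(rbind, res)
  out[order(out$class), , drop = FALSE]
}

# majority (modal) allele per site within a group of haplotype rows;
# NA where no non-missing call
majority_allele <- function(a) {
  n1 <- colSums(a == 1L, na.rm = TRUE)
  n0 <- colSums(a == 0L, na.rm = TRUE)
  out <- ifelse(n1 > n0, 1L, 0L)
  out[n1 + n0 == 0] <- NA_integer_
  out
}

#' Exclude failed-cross and recombinant haplotypes
#'
#' Applies the two exclusion rules used before class assignment:
#' haplotypes whose source F1 genotype calls were homozygous at every site
#' (`het_fraction == 0`) indicate a failed cross and are excluded as
#' `excluded:homozygous`; haplotypes whose alleles switch between
#' class-1-type and class-2-type along the chromosome (at least `min_block`
#' consecutive diagnostic sites of each type) are inter-class recombinants
#' and are excluded as `excluded:recombinant`, so that marker SNPs remain
#' unambiguous.
#'
#' Diagnostic sites are those where the majority alleles of the two
#' provisional clusters differ. If no provisional labels are supplied, the
#' haplotypes are clustered into two groups by average-linkage on the
#' fraction of differing non-missing sites.
#'
#' @param x A `HaplotypeMatrix`.
#' @param provisional Optional vector of provisional group labels (two
#'   levels), one per haplotype.
#' @param min_block Minimum run of consecutive diagnostic sites of each type
#'   for a haplotype to count as recombinant (default 5).
#' @return data.frame with columns `haplotype_id`, `status`
#'   (`"retained"`, `"excluded:homozygous"` or `"excluded:recombinant"`) and
#'   `provisional` (1/2 cluster label, NA for excluded haplotypes).
#' @export
exclude_failed_and_recombinant <- function(x, provisional = NULL,
                                           min_block = 5L) {
  n <- nrow(x$alleles)
  if (n < 3) stopf("insufficient data: need at least 3 haplotypes")
  status <- rep("retained", n)
  # failed crosses: all-homozygous source genotypes
  if (!is.null(x$het_fraction)) {
    status[!is.na(x$het_fraction) & x$het_fraction == 0] <-
      "excluded:homozygous"
  }
  ok <- status == "retained"
  if (sum(ok) < 3) stopf("insufficient data: fewer than 3 usable haplotypes")
  sub <- hap_subset(x, which(ok))
  if (is.null(provisional)) {
    grp <- cluster_haplotypes(sub, k = 2L)$groups
  } else {
    if (length(provisional) != n) {
      stopf("provisional labels must have one entry per haplotype")
    }
    grp <- as.integer(factor(provisional[ok]))
    if (length(unique(grp)) != 2) stopf("provisional labels must have 2 levels")
  }
  a <- sub$alleles
  maj1 <- majority_allele(a[grp == 1L, , drop = FALSE])
  maj2 <- majority_allele(a[grp == 2L, , drop = FALSE])
  diag_sites <- which(!is.na(maj1) & !is.na(maj2) & maj1 != maj2)
  if (length(diag_sites) > 0) {
    for (i in seq_len(nrow(a))) {
      v <- a[i, diag_sites]
      type <- ifelse(v == maj1[diag_sites], 1L,
                     ifelse(v == maj2[diag_sites], 2L, NA_integer_))
      type <- type[!is.na(type)]
      if (!length(type)) next
      r <- rle(type)
      if (any(r$lengths >= min_block & r$values == 1L) &&
          any(r$lengths >= min_block & r$values == 2L)) {
        status[which(ok)[i]] <- "excluded:recombinant"
      }
    }
  }
  prov <- rep(NA_integer_, n)
  prov[which(ok)] <- grp
  prov[status != "retained"] <- NA_integer_
  data.frame(haplotype_id = x$ids, status = status, provisional = prov,
             stringsAsFactors = FALSE)
}

# locate resistance sites (data.frame with chrom, pos) in a site table
match_sites <- function(sites, targets, what = "site") {
  idx <- match(site_key(targets), site_key(sites))
  if (anyNA(idx)) {
    miss <- site_key(targets)[is.na(idx)]
    stopf("%s %s not found", what, paste(miss, collapse = ", "))
  }
  idx
}

#' Assign founder haplotypes to classes 1a, 1b and 2
#'
#' Retained haplotypes are grouped into two top-level classes by
#' average-linkage agglomerative clustering on the fraction of differing
#' non-missing sites, cut into two groups; the cut is validated by requiring
#' the mean between-group divergence to exceed the larger mean within-group
#' divergence (otherwise an ambiguous-structure error is raised with
#' diagnostics). Class 1 is the group containing haplotypes that carry the
#' alternative allele at all three resistance sites (falling back to the
#' less diverse group if no carrier exists). Within class 1, haplotypes
#' carrying all three resistance alleles are labeled `1a` and haplotypes
#' carrying none `1b`. A haplotype carrying a strict subset of the
#' resistance alleles contradicts the expected structure and raises an error
#' by default (`anomalous = "flag"` labels it `anomalous` instead).
#'
#' @param x A `HaplotypeMatrix`.
#' @param resistance_sites data.frame with columns `chrom`, `pos` giving the
#'   three linked resistance sites (the alternative allele is the resistance
#'   allele).
#' @param exclusions Result of [exclude_failed_and_recombinant()]; computed
#'   automatically if `NULL`.
#' @param min_block Passed to [exclude_failed_and_recombinant()].
#' @param anomalous `"error"` (default) or `"flag"`: handling of haplotypes
#'   with a strict subset of resistance alleles.
#' @return A `ClassAssignment`: data.frame with columns `haplotype_id`,
#'   `label` (one of `1a`, `1b`, `2`, `excluded:homozygous`,
#'   `excluded:recombinant`, `anomalous`), plus the resistance sites in
#'   `attr(, "resistance_sites")`.
#' @export
assign_classes <- function(x, resistance_sites, exclusions = NULL,
                           min_block = 5L,
                           anomalous = c("error", "flag")) {
  anomalous <- match.arg(anomalous)
  if (is.null(exclusions)) {
    exclusions <- exclude_failed_and_recombinant(x, min_block = min_block)
  }
  res_idx <- match_sites(x$sites, resistance_sites, "resistance site")
  keep <- exclusions$status == "retained"
  sub <- hap_subset(x, which(keep))
  cl <- cluster_haplotypes(sub, k = 2L)
  grp <- cl$groups
  # separation diagnostic for the two-group cut
  dv <- as.matrix(hap_divergence(sub))
  within <- vapply(1:2, function(g) {
    m <- dv[grp == g, grp == g, drop = FALSE]
    if (nrow(m) < 2) 0 else mean(m[upper.tri(m)], na.rm = TRUE)
  }, numeric(1))
  between <- mean(dv[grp == 1, grp == 2, drop = FALSE], na.rm = TRUE)
  if (!is.finite(between) || between <= max(within)) {
    stopf(paste0("ambiguous haplotype structure: mean between-group ",
                 "divergence (%.4g) does not exceed within-group ",
                 "divergence (%.4g, %.4g)"),
          between, within[1], within[2])
  }
  nres <- rowSums(sub$alleles[, res_idx, drop = FALSE] == 1L, na.rm = TRUE)
  carrier <- nres == length(res_idx)
  has_carrier <- vapply(1:2, function(g) any(carrier[grp == g]), logical(1))
  if (all(has_carrier)) {
    stopf("ambiguous haplotype structure: both top-level groups contain full resistance-allele carriers")
  }
  class1 <- if (any(has_carrier)) which(has_carrier) else which.min(within)
  lab <- ifelse(grp == class1,
                ifelse(carrier, "1a", ifelse(nres == 0, "1b", "anomalous")),
                ifelse(nres == 0, "2", "anomalous"))
  if (any(lab == "anomalous") && anomalous == "error") {
    bad <- sub$ids[lab == "anomalous"]
    stopf(paste0("haplotype(s) %s carry a strict subset of the resistance ",
                 "alleles, contradicting the expected class structure ",
                 "(use anomalous = \"flag\" to keep them)"),
          paste(bad, collapse = ", "))
  }
  label <- exclusions$status
  label[keep] <- lab
  out <- data.frame(haplotype_id = x$ids, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "resistance_sites") <- x$sites[res_idx, , drop = FALSE]
  attr(out, "separation") <- c(between = between, within = within)
  class(out) <- c("ClassAssignment", "data.frame")
  out
}

#' Discover diagnostic marker SNPs between haplotype classes 1 and 2
#'
#' A marker SNP is a site at which every retained class-1 haplotype (1a and
#' 1b) carries one allele and every retained class-2 haplotype carries the
#' other, so class-1 frequency can be read off pooled data unambiguously.
#' Missing calls are ignored, but a single conflicting call disqualifies the
#' site; both classes must have at least one non-missing call. Resistance
#' sites are excluded from the marker set (they tag 1a within class 1).
#'
#' @param x A `HaplotypeMatrix`.
#' @param assignment A `ClassAssignment` from [assign_classes()].
#' @return A `MarkerSet`: data.frame of sites (`chrom`, `pos`, `ref`, `alt`)
#'   with column `class1_allele` (0/1, the allele tagging class 1).
#' @export
find_marker_snps <- function(x, assignment) {
  lab <- assignment$label[match(x$ids, assignment$haplotype_id)]
  i1 <- which(lab %in% c("1a", "1b"))
  i2 <- which(lab == "2")
  if (!length(i1) || !length(i2)) {
    stopf("both class 1 and class 2 must contain retained haplotypes")
  }
  a1 <- x$alleles[i1, , drop = FALSE]
  a2 <- x$alleles[i2, , drop = FALSE]
  n1_1 <- colSums(a1 == 1L, na.rm = TRUE)
  n1_0 <- colSums(a1 == 0L, na.rm = TRUE)
  n2_1 <- colSums(a2 == 1L, na.rm = TRUE)
  n2_0 <- colSums(a2 == 0L, na.rm = TRUE)
  fixed1 <- (n1_1 == 0 | n1_0 == 0) & (n1_1 + n1_0 >= 1)
  fixed2 <- (n2_1 == 0 | n2_0 == 0) & (n2_1 + n2_0 >= 1)
  al1 <- ifelse(n1_1 > 0, 1L, 0L)
  al2 <- ifelse(n2_1 > 0, 1L, 0L)
  is_marker <- fixed1 & fixed2 & al1 != al2
  res <- attr(assignment, "resistance_sites")
  if (!is.null(res)) {
    is_marker[match_sites(x$sites, res, "resistance site")] <- FALSE
  }
  out <- x$sites[is_marker, , drop = FALSE]
  out$class1_allele <- al1[is_marker]
  rownames(out) <- NULL
  class(out) <- c("MarkerSet", "data.frame")
  out
}
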