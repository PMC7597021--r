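#' Filter Pool-seq SNPs on minor allele count and coverage
#'
#' Retains sites whose minor allele count (the smaller of the total reference
#' and total alternative read counts summed over all samples) is at least
#' `min_mac`, and whose coverage is at least `min_coverage` in every sample.
#' An exclusion report (site, reason) is attached as attribute `"excluded"`.
#'
#' @param x An `AlleleCountTable`.
#' @param min_mac Minimum minor allele count across all samples (default 5).
#' @param min_coverage Minimum per-sample coverage (default 10).
#' @return Filtered `AlleleCountTable` (warns, but does not error, if no
#'   site survives).
#' @export
filter_snps <- function(x, min_mac = 5L, min_coverage = 10L) {
  cov <- act_coverage(x)
  tot_alt <- colSums(act_allele_counts(x, "alt"))
  tot_ref <- colSums(act_allele_counts(x, "ref"))
  mac <- pmin(tot_alt, tot_ref)
  low_cov <- apply(cov < min_coverage, 2, any)
  low_mac <- mac < min_mac
  reason <- rep(NA_character_, nrow(x$sites))
  reason[low_mac] <- "low minor allele count"
  reason[low_cov] <- "insufficient coverage"  # coverage reason takes priority
  keep <- !(low_cov | low_mac)
  excluded <- cbind(x$sites[!keep, c("chrom", "pos"), drop = FALSE],
                    reason = reason[!keep])
  rownames(excluded) <- NULL
  if (!any(keep)) warnf("no SNP passed the filters")
  out <- act_subset(x, sites = which(keep))
  attr(out, "excluded") <- excluded
  out
}

#' Haplotype-class frequency trajectories from marker SNPs
#'
#' Per sample, the class-1 frequency `f_1` is the median over usable marker
#' SNPs of the class-1-allele frequency; the class-1a frequency `f_1a` is the
#' median of the three resistance-allele (alternative) frequencies;
#' `f_1b = f_1 - f_1a`, clamped to `[0, f_1]` (negative sampling-noise
#' differences are clamped at 0 and counted); `f_2 = 1 - f_1`. The triple is
#' then renormalized to sum to 1; raw values are reported alongside. With an
#' even marker count the median is the mean of the two central order
#' statistics. Markers absent from the (filtered) table are dropped for all
#' samples of the table, mirroring regime-wide marker exclusion.
#'
#' @param x An `AlleleCountTable`, typically already passed through
#'   [filter_snps()]; one regime per call.
#' @param markers A `MarkerSet` from [find_marker_snps()].
#' @param resistance_sites data.frame (`chrom`, `pos`) of the three
#'   resistance sites; all must be present in `x`, otherwise the estimator is
#'   undefined and an error is raised.
#' @return A `ClassTrajectorySet`: tidy data.frame with columns `replicate`,
#'   `generation`, `regime`, `class` (1a/1b/2), `frequency` (normalized),
#'   `frequency_raw`, `n_markers`. Attributes: `markers_used`,
#'   `n_markers_dropped`, `n_clamped`.
#' @export
class_frequencies <- function(x, markers, resistance_sites) {
  res_idx <- tryCatch(match_sites(x$sites, resistance_sites,
                                  "resistance site"),
                      error = function(e) {
                        stopf("haplotype-class estimator undefined: %s",
                              conditionMessage(e))
                      })
  mk_idx <- match(site_key(markers), site_key(x$sites))
  dropped <- sum(is.na(mk_idx))
  usable <- which(!is.na(mk_idx))
  if (!length(usable)) stopf("no usable marker SNP present in the table")
  mk_idx <- mk_idx[usable]
  class1_allele <- markers$class1_allele[usable]
  f <- act_alt_freq(x)
  n_samp <- nrow(x$samples)
  out <- vector("list", n_samp)
  n_clamped <- 0L
  for (i in seq_len(n_samp)) {
    mf <- f[i, mk_idx]
    cf <- ifelse(class1_allele == 1L, mf, 1 - mf)
    f1 <- stats::median(cf, na.rm = TRUE)
    f1a <- stats::median(f[i, res_idx], na.rm = TRUE)
    f1b_raw <- f1 - f1a
    f1b <- clamp(f1b_raw, 0, f1)
    if (f1b != f1b_raw) n_clamped <- n_clamped + 1L
    raw <- c(`1a` = f1a, `1b` = f1b_raw, `2` = 1 - f1)
    tri <- c(`1a` = f1a, `1b` = f1b, `2` = 1 - f1)
    norm <- tri / sum(tri)
    out[[i]] <- data.frame(replicate = x$samples$replicate[i],
                           generation = x$samples$generation[i],
                           regime = x$samples$regime[i],
                           class = names(norm),
                           frequency = as.numeric(norm),
                           frequency_raw = as.numeric(raw),
                           n_markers = length(mk_idx),
                           stringsAsFactors = FALSE)
  }
  traj <- do.call(rbind, out)
  rownames(traj) <- NULL
  if (n_clamped > 0) {
    message(sprintf("class_frequencies: clamped f_1b in %d of %d samples",
                    n_clamped, n_samp))
  }
  attr(traj, "markers_used") <- markers[usable, , drop = FALSE]
  attr(traj, "n_markers_dropped") <- dropped
  attr(traj, "n_clamped") <- n_clamped
  class(traj) <- c("ClassTrajectorySet", "data.frame")
  traj
}

#' Extract one replicate/class trajectory
#'
#' @param traj A `ClassTrajectorySet`.
#' @param replicate Replicate id.
#' @param class Class label (`"1a"`, `"1b"` or `"2"`).
#' @param raw Use raw (un-renormalized) frequencies.
#' @return data.frame with columns `generation`, `frequency`, sorted by
#'   generation.
#' @export
class_trajectory <- function(traj, replicate, class, raw = FALSE) {
  sel <- traj$replicate == replicate & traj$class == class
  if (!any(sel)) stopf("no trajectory for replicate '%s' class '%s'",
                       replicate, class)
  d <- traj[sel, , drop = FALSE]
  d <- d[order(d$generation), , drop = FALSE]
  data.frame(generation = d$generation,
             frequency = if (raw) d$frequency_raw else d$frequency)
}
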