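#' Allele count tables from Pool-seq sync files
#'
#' An `AlleleCountTable` holds per (sample x site) nucleotide read counts as
#' parsed from a PoPoolation2 sync file, together with site metadata
#' (chromosome, position, reference and alternative allele) and sample
#' annotations (replicate, generation, regime). Counts for all six sync
#' fields (`A:T:C:G:N:del`) are retained so files round-trip exactly; `N`
#' and deletion counts are excluded from coverage.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param samples data.frame with columns `replicate`, `generation` and
#'   optionally `regime`.
#' @param counts integer array of dimension `n_samples x n_sites x 6`, third
#'   dimension named `A,T,C,G,N,del`.
#' @return An object of class `AlleleCountTable`.
#' @export
allele_count_table <- function(sites, samples, counts) {
  sites <- as.data.frame(sites)
  samples <- as.data.frame(samples)
  check_sites(sites)
  if (!all(c("replicate", "generation") %in% names(samples))) {
    stopf("sample table needs columns replicate, generation")
  }
  if (is.null(samples$regime)) samples$regime <- NA_character_
  if (length(dim(counts)) != 3 ||
      dim(counts)[1] != nrow(samples) ||
      dim(counts)[2] != nrow(sites) ||
      dim(counts)[3] != 6) {
    stopf("counts must be an array of dim n_samples x n_sites x 6")
  }
  dimnames(counts) <- list(NULL, NULL, SYNC_NUC)
  if (any(counts < 0)) stopf("all counts must be non-negative")
  ord <- site_order(sites)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  counts <- counts[, ord, , drop = FALSE]
  # generations must be non-decreasing within each replicate
  for (r in unique(samples$replicate)) {
    g <- samples$generation[samples$replicate == r]
    if (is.unsorted(g)) {
      stopf("generations are not non-decreasing within replicate '%s'", r)
    }
  }
  structure(list(sites = sites, samples = samples, counts = counts),
            class = "AlleleCountTable")
}

#' @export
print.AlleleCountTable <- function(x, ...) {
  cat(sprintf("AlleleCountTable: %d sites x %d samples\n",
              nrow(x$sites), nrow(x$samples)))
  cat(sprintf("  chrom(s): %s; positions %d-%d\n",
              paste(unique(x$sites$chrom), collapse = ","),
              min(x$sites$pos), max(x$sites$pos)))
  cat(sprintf("  replicates: %s; generations: %s\n",
              paste(unique(x$samples$replicate), collapse = ","),
              paste(unique(x$samples$generation), collapse = ",")))
  invisible(x)
}

slice_nuc <- function(counts, nuc) {
  out <- counts[, , nuc, drop = FALSE]
  dim(out) <- dim(counts)[1:2]
  out
}

#' Per-sample, per-site read coverage (A+T+C+G)
#'
#' @param x An `AlleleCountTable`.
#' @return Matrix `n_samples x n_sites`.
#' @export
act_coverage <- function(x) {
  slice_nuc(x$counts, "A") + slice_nuc(x$counts, "T") +
    slice_nuc(x$counts, "C") + slice_nuc(x$counts, "G")
}

#' Reference or alternative allele read counts
#'
#' @param x An `AlleleCountTable`.
#' @param which `"alt"` or `"ref"`.
#' @return Matrix `n_samples x n_sites`.
#' @export
act_allele_counts <- function(x, which = c("alt", "ref")) {
  which <- match.arg(which)
  al <- if (which == "alt") x$sites$alt else x$sites$ref
  ns <- nrow(x$samples)
  nj <- nrow(x$sites)
  idx <- cbind(rep(seq_len(ns), times = nj),
               rep(seq_len(nj), each = ns),
               rep(match(al, SYNC_NUC), each = ns))
  matrix(x$counts[idx], nrow = ns, ncol = nj)
}

#' Alternative-allele frequencies
#'
#' Frequencies are `NA` where coverage is zero.
#'
#' @param x An `AlleleCountTable`.
#' @return Matrix `n_samples x n_sites` of frequencies in `[0, 1]`.
#' @export
act_alt_freq <- function(x) {
  cov <- act_coverage(x)
  f <- act_allele_counts(x, "alt") / cov
  f[cov == 0] <- NA_real_
  f
}

#' Subset an allele count table
#'
#' @param x An `AlleleCountTable`.
#' @param sites,samples Index vectors (integer or logical) into sites and
#'   samples; `NULL` keeps all.
#' @return An `AlleleCountTable`.
#' @export
act_subset <- function(x, sites = NULL, samples = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(x$samples)) else samples
  sj <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  allele_count_table(x$sites[sj, , drop = FALSE],
                     x$samples[si, , drop = FALSE],
                     x$counts[si, sj, , drop = FALSE])
}

#' Read a PoPoolation2 sync file
#'
#' Parses a tab- (or space-) separated sync file with columns chrom, pos, ref
#' followed by one `A:T:C:G:N:del` count column per sample. The alternative
#' allele at each site is defined globally: the non-reference nucleotide with
#' the highest read count summed over all samples, ties broken by
#' alphabetical order, so that frequencies are comparable across generations.
#'
#' @param path Path to the sync file.
#' @param samples data.frame annotating the sample columns in file order;
#'   needs `replicate`, `generation` and optionally `regime` columns. The
#'   number of rows must equal the number of sample columns.
#' @return An `AlleleCountTable` with sites ordered by (chrom, pos).
#' @export
read_sync <- function(path, samples) {
  samples <- as.data.frame(samples)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stopf("sync file '%s' contains no data lines", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols != ncols[1])) {
    i <- which(ncols != ncols[1])[1]
    stopf("sync parse error at line %d: expected %d columns, found %d",
          line_no[i], ncols[1], ncols[i])
  }
  n_samp <- ncols[1] - 3L
  if (n_samp < 1) {
    stopf("configuration error: sync file '%s' has no sample columns", path)
  }
  if (nrow(samples) != n_samp) {
    stopf("configuration error: %d sample annotations supplied for %d sample columns",
          nrow(samples), n_samp)
  }
  m <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  chrom <- m[, 1]
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) {
    stopf("sync parse error at line %d: position '%s' is not an integer",
          line_no[which(is.na(pos))[1]], m[which(is.na(pos))[1], 2])
  }
  ref <- toupper(m[, 3])
  if (!all(ref %in% ACGT)) {
    i <- which(!ref %in% ACGT)[1]
    stopf("sync parse error at line %d: reference allele '%s'",
          line_no[i], ref[i])
  }
  n_site <- length(lines)
  counts <- array(0L, dim = c(n_samp, n_site, 6L),
                  dimnames = list(NULL, NULL, SYNC_NUC))
  for (k in seq_len(n_samp)) {
    parts <- strsplit(m[, 3L + k], ":", fixed = TRUE)
    bad <- lengths(parts) != 6L
    if (any(bad)) {
      i <- which(bad)[1]
      stopf("sync parse error at line %d: malformed count column '%s'",
            line_no[i], m[i, 3L + k])
    }
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v)) {
      i <- ceiling(which(is.na(v))[1] / 6)
      stopf("sync parse error at line %d: non-integer count in column '%s'",
            line_no[i], m[i, 3L + k])
    }
    counts[k, , ] <- matrix(v, ncol = 6L, byrow = TRUE)
  }
  # global alternative allele: max summed non-reference count, ties -> A<C<G<T
  tot <- sapply(ACGT, function(nuc) colSums(slice_nuc(counts, nuc)))
  if (n_site == 1L) tot <- matrix(tot, nrow = 1, dimnames = list(NULL, ACGT))
  tot[cbind(seq_len(n_site), match(ref, ACGT))] <- -1
  alt <- ACGT[max.col(tot, ties.method = "first")]
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  allele_count_table(sites, samples, counts)
}

#' Write an allele count table as a PoPoolation2 sync file
#'
#' @param x An `AlleleCountTable`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  ns <- nrow(x$samples)
  cols <- lapply(seq_len(ns), function(k) {
    ck <- matrix(x$counts[k, , ], ncol = 6L)
    apply(ck, 1, paste, collapse = ":")
  })
  lines <- do.call(paste, c(list(x$sites$chrom, x$sites$pos, x$sites$ref),
                            cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
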