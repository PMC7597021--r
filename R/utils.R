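# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible child seed from a master seed
#'
#' Child streams (per replicate, per stage) are derived deterministically so
#' that one master seed reproduces a whole experiment bit-for-bit. Values stay
#' below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param ... Integer offsets identifying the stream (e.g. stage, replicate).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  s <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (k in c(...)) {
    s <- (s * 48271 + abs(as.double(k)) + 1) %% 2147483647
  }
  as.integer(s)
}

# Nucleotide column order of the PoPoolation2 sync dialect
SYNC_NUC <- c("A", "T", "C", "G", "N", "del")
ACGT <- c("A", "C", "G", "T")

check_sites <- function(sites) {
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(sites))) {
    stopf("site table needs columns %s", paste(req, collapse = ", "))
  }
  if (any(sites$pos < 1)) stopf("site positions must be >= 1 (1-based)")
  if (!all(sites$ref %in% ACGT) || !all(sites$alt %in% ACGT)) {
    stopf("ref and alt alleles must be one of A/C/G/T")
  }
  if (any(sites$ref == sites$alt)) stopf("ref and alt alleles must differ")
  invisible(sites)
}

# order sites by (chrom, pos); returns permutation
site_order <- function(sites) order(sites$chrom, sites$pos)

site_key <- function(x) paste(x$chrom, x$pos, sep = ":")

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
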