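# fixture builders used across test files; everything is generated in code

# an allele count table holding only ref/alt reads
make_act <- function(alt, cov, samples, chrom = "3R", pos = NULL,
                     ref = "A", alt_allele = "C") {
  alt <- as.matrix(alt)
  cov <- as.matrix(cov)
  n_samp <- nrow(alt)
  n_site <- ncol(alt)
  pos <- pos %||% seq_len(n_site) * 1000L
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep_len(ref, n_site),
                      alt = rep_len(alt_allele, n_site))
  counts <- array(0L, dim = c(n_samp, n_site, 6L),
                  dimnames = list(NULL, NULL, c("A", "T", "C", "G", "N", "del")))
  for (j in seq_len(n_site)) {
    counts[, j, sites$alt[j]] <- alt[, j]
    counts[, j, sites$ref[j]] <- cov[, j] - alt[, j]
  }
  allele_count_table(sites, samples, counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small table for round-trip properties; every site gets at least one
# alternative read somewhere so the global alt-allele rule re-derives the
# same alt on re-reading
random_act <- function(seed, n_samp = 3, n_site = 8) {
  set.seed(seed)
  sites <- data.frame(chrom = sample(c("2L", "3R"), n_site, replace = TRUE),
                      pos = sample.int(1e6, n_site),
                      ref = sample(c("A", "C", "G", "T"), n_site,
                                   replace = TRUE))
  sites$alt <- vapply(sites$ref,
                      function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                      character(1))
  samples <- data.frame(replicate = rep(1L, n_samp),
                        generation = sort(sample.int(60, n_samp)),
                        regime = "hot")
  counts <- array(0L, dim = c(n_samp, n_site, 6L),
                  dimnames = list(NULL, NULL, c("A", "T", "C", "G", "N", "del")))
  for (j in seq_len(n_site)) {
    cov <- sample(20:90, n_samp)
    a <- pmax(rbinom(n_samp, cov, 0.3), c(1L, rep(0L, n_samp - 1)))
    counts[, j, sites$alt[j]] <- a
    counts[, j, sites$ref[j]] <- cov - a
    counts[, j, "N"] <- sample(0:2, n_samp, replace = TRUE)
  }
  allele_count_table(sites, samples, counts)
}

# hand-built haplotype matrix; rows of `alleles` are haplotypes
make_hapmatrix <- function(alleles, L = 100, chrom = "3R", pos = NULL,
                           het_fraction = NULL) {
  alleles <- as.matrix(alleles)
  n_site <- ncol(alleles)
  pos <- pos %||% seq_len(n_site) * 10L
  sites <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G")
  haplotype_matrix(sites, alleles, L = L, het_fraction = het_fraction)
}

# a small three-class founder configuration that keeps simulations fast;
# the gene window shrinks with the site count so per-site diversity targets
# stay attainable
small_config <- function(seed, ...) {
  sim_config(seed = seed,
             n_haplotypes = c(`1a` = 6L, `1b` = 4L, `2` = 4L),
             n_marker_snps = 30L, n_extra_sites = 400L, L = 4000L, ...)
}

# brute-force nucleotide diversity: explicit double loop over pairs
pi_bruteforce <- function(alleles, L) {
  n <- nrow(alleles)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(abs(alleles[i, ] - alleles[j, ]), na.rm = TRUE)
    }
  }
  (tot / (n * (n - 1) / 2)) / L
}

# minimal founder-haplotype VCF text for reader tests
write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=3R>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "hapA", "hapB", "hapC"), collapse = "\t"),
    "3R\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1\t0/0\t1/1",
    "3R\t200\t.\tC\tT\t50\tPASS\t.\tGT\t0|1\t./.\t0/0",
    "3R\t300\t.\tG\tA,T\t50\tPASS\t.\tGT\t0/1\t0/2\t0/0",
    "3R\t400\t.\tT\tTA\t50\tPASS\t.\tGT\t0/1\t0/0\t0/0",
    "3R\t500\t.\tG\tC\t50\tPASS\t.\tGT\t1/0\t0/0\t0/0",
    "3R\t9000\t.\tA\tC\t50\tPASS\t.\tGT\t0/1\t0/1\t0/0")
  writeLines(lines, path)
  path
}
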