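#' Configuration of a synthetic Evolve-and-Resequence experiment
#'
#' Bundles every parameter of the simulated experiment: a founder population
#' of three haplotype classes (1a carries the three linked resistance
#' alleles; 1b is its nearly identical susceptible sister; 2 is a diverse
#' susceptible class), diploid Wright-Fisher reproduction with per-class
#' co-dominant selection, Pool-seq sampling and probit bioassay mortality.
#'
#' The defaults reproduce the study conditions: founder class frequencies
#' (0.59, 0.25, 0.16); per-regime class selection coefficients relative to 1b
#' of (-0.031, 0, +0.0527) in the hot regime and (-0.055, 0, +0.0935) in the
#' cold regime (the class-2 advantage is 1.7 times the 1a-1b difference);
#' replicate-specific effective sizes 252/229/268/209/245 (hot) and
#' 209/255/259/198/175 (cold); census and pool size 1000 flies; sampling at
#' generations 0/15/37/59 (hot) and 0/11/21/31/41/51 (cold); a founder panel
#' of 19 + 8 + 5 haplotypes; 166 diagnostic marker SNPs; within-class
#' diversity targets pi = 0.0004 (class 1) and 0.0082 (class 2) over
#' L = 36,265 bp; Poisson mean read coverage 80.
#'
#' @param founder_class_freqs Named simplex vector of founder frequencies for
#'   classes `1a`, `1b`, `2` (must sum to 1 within 1e-12).
#' @param class_s Named list (one element per regime) of per-class selection
#'   coefficients; class fitness is `1 + s`.
#' @param h Dominance coefficient in `[0, 1]` (0.5 = co-dominance).
#' @param census_N Census population size (flies).
#' @param effective_Ne Named list (per regime) of per-replicate effective
#'   sizes (diploids); may contain `Inf` for deterministic evolution.
#' @param n_replicates Number of replicate populations per regime.
#' @param sampled_generations Named list (per regime) of sampled generations;
#'   each must start at 0 and strictly increase.
#' @param n_haplotypes Named vector: founder-panel haplotypes per class.
#' @param n_marker_snps Number of diagnostic sites fixed-different between
#'   class 1 and class 2.
#' @param within_class_pi Length-2 vector: target nucleotide diversity within
#'   class 1 and within class 2.
#' @param n_extra_sites Sites available for within-class private variation.
#' @param chrom,gene_start Chromosome and 1-based start of the simulated gene
#'   region; all sites fall in `[gene_start, gene_start + L - 1]`.
#' @param L Gene length in bp (diversity denominator).
#' @param mean_coverage Mean Pool-seq read coverage (Poisson).
#' @param pool_size Individuals pooled for sequencing (default `census_N`).
#' @param seed Master RNG seed; all child streams derive from it.
#' @return An object of class `SimConfig` (a validated list).
#' @export
sim_config <- function(founder_class_freqs = c(`1a` = 0.59, `1b` = 0.25,
                                               `2` = 0.16),
                       class_s = list(
                         hot = c(`1a` = -0.031, `1b` = 0, `2` = 1.7 * 0.031),
                         cold = c(`1a` = -0.055, `1b` = 0, `2` = 1.7 * 0.055)),
                       h = 0.5,
                       census_N = 1000L,
                       effective_Ne = list(hot = c(252, 229, 268, 209, 245),
                                           cold = c(209, 255, 259, 198, 175)),
                       n_replicates = 5L,
                       sampled_generations = list(hot = c(0, 15, 37, 59),
                                                  cold = c(0, 11, 21, 31, 41, 51)),
                       n_haplotypes = c(`1a` = 19L, `1b` = 8L, `2` = 5L),
                       n_marker_snps = 166L,
                       within_class_pi = c(class1 = 4e-04, class2 = 82e-04),
                       n_extra_sites = 4000L,
                       chrom = "3R",
                       gene_start = 11989000L,
                       L = 36265L,
                       mean_coverage = 80,
                       pool_size = NULL,
                       seed = 1L) {
  classes <- c("1a", "1b", "2")
  if (!identical(names(founder_class_freqs), classes)) {
    stopf("founder_class_freqs must be named %s", paste(classes, collapse = ","))
  }
  if (abs(sum(founder_class_freqs) - 1) > 1e-12) {
    stopf("founder class frequencies must sum to 1 (got %.15g)",
          sum(founder_class_freqs))
  }
  if (any(founder_class_freqs < 0)) stopf("class frequencies must be >= 0")
  regimes <- names(class_s)
  if (is.null(regimes) || !length(regimes)) stopf("class_s must be a named list")
  for (rg in regimes) {
    if (!identical(names(class_s[[rg]]), classes)) {
      stopf("class_s$%s must be named %s", rg, paste(classes, collapse = ","))
    }
    if (any(1 + class_s[[rg]] <= 0)) {
      stopf("all class fitness values (1 + s) must be > 0 in regime %s", rg)
    }
    sg <- sampled_generations[[rg]]
    if (is.null(sg) || sg[1] != 0 || any(diff(sg) <= 0)) {
      stopf("sampled generations for regime %s must start at 0 and strictly increase", rg)
    }
    ne <- effective_Ne[[rg]]
    if (is.null(ne) || length(ne) != n_replicates || any(ne <= 0)) {
      stopf("effective_Ne$%s must give %d positive values", rg, n_replicates)
    }
  }
  if (h < 0 || h > 1) stopf("dominance h must lie in [0, 1]")
  if (census_N < 1) stopf("census_N must be positive")
  if (n_marker_snps < 1) stopf("n_marker_snps must be positive")
  if (length(within_class_pi) != 2 || any(within_class_pi < 0)) {
    stopf("within_class_pi must be two non-negative values (class 1, class 2)")
  }
  if (n_marker_snps + 3L + n_extra_sites > L) {
    stopf("configuration error: %d sites exceed the %d bp gene window",
          n_marker_snps + 3L + n_extra_sites, L)
  }
  if (mean_coverage <= 0) stopf("mean_coverage must be positive")
  structure(list(founder_class_freqs = founder_class_freqs,
                 class_s = class_s, h = h,
                 census_N = as.integer(census_N),
                 effective_Ne = effective_Ne,
                 n_replicates = as.integer(n_replicates),
                 sampled_generations = sampled_generations,
                 n_haplotypes = n_haplotypes,
                 n_marker_snps = as.integer(n_marker_snps),
                 within_class_pi = within_class_pi,
                 n_extra_sites = as.integer(n_extra_sites),
                 chrom = chrom, gene_start = as.integer(gene_start),
                 L = as.integer(L),
                 mean_coverage = mean_coverage,
                 pool_size = as.integer(pool_size %||% census_N),
                 regimes = regimes,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a founder haplotype panel with three classes
#'
#' Builds class archetypes on randomly placed biallelic sites inside the gene
#' window: classes 1a and 1b are identical except at three linked resistance
#' sites where 1a carries the alternative allele; class 2 differs from class
#' 1 at `n_marker_snps` diagnostic sites (random polarity per site).
#' Within-class variation is added as per-haplotype private mutations on
#' non-marker, non-resistance sites, with a Poisson mean of `pi * L / 2`
#' mutations per haplotype so the expected pairwise diversity matches the
#' per-class target. Optionally appends failed-cross haplotypes (all
#' homozygous source calls) and class-1/class-2 chimeras, emulating the
#' haplotypes excluded in a real panel.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (default: derived from `config$seed`).
#' @param n_failed Failed-cross haplotypes to append (het_fraction 0).
#' @param n_recombinant Inter-class chimeric haplotypes to append.
#' @return List with `haplotypes` (a [haplotype_matrix()]), and `truth`: class
#'   labels (including `"failed"`/`"recombinant"` for appended haplotypes),
#'   resistance and marker site tables, founder class frequencies and seed.
#' @export
simulate_founder <- function(config, seed = derive_seed(config$seed, 1),
                             n_failed = 0L, n_recombinant = 0L) {
  set.seed(seed)
  nm <- config$n_marker_snps
  ne <- config$n_extra_sites
  n_sites <- 3L + nm + ne
  pos <- sort(sample.int(config$L, n_sites)) + config$gene_start - 1L
  role <- sample(rep(c("resistance", "marker", "extra"), c(3L, nm, ne)))
  ref <- sample(ACGT, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(ACGT, r), 1), character(1))
  sites <- data.frame(chrom = config$chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  res_i <- which(role == "resistance")
  mk_i <- which(role == "marker")
  ex_i <- which(role == "extra")
  # class-1 archetype: random polarity at marker sites, 0 elsewhere
  arch1 <- integer(n_sites)
  arch1[mk_i] <- stats::rbinom(nm, 1L, 0.5)
  arch2 <- arch1
  arch2[mk_i] <- 1L - arch1[mk_i]
  arch1a <- arch1
  arch1a[res_i] <- 1L  # resistance alleles are the alternative alleles
  counts <- config$n_haplotypes
  labels <- rep(names(counts), counts)
  # Poisson mean of private mutations per haplotype, calibrated so the
  # expected realized pi matches the per-class target: a pair of haplotypes
  # with Poisson(mu) flips over ne candidate sites differs at
  # ~ 2 mu (1 - mu/ne) sites (collisions cancel), and class 1 additionally
  # carries the fixed 1a/1b difference at the three resistance sites.
  mu_for_pi <- function(pi_target) {
    dbar <- pi_target * config$L
    if (dbar <= 0) return(0)
    if (2 * dbar / ne >= 1) return(ne / 2)  # saturation guard
    ne * (1 - sqrt(1 - 2 * dbar / ne)) / 2
  }
  n1a <- sum(labels == "1a")
  n1b <- sum(labels == "1b")
  n1 <- n1a + n1b
  res_contrib <- if (n1 >= 2) 3 * (n1a * n1b) / (n1 * (n1 - 1) / 2) else 0
  pi1_adj <- max(config$within_class_pi[1] - res_contrib / config$L, 0)
  mu <- ifelse(labels == "2",
               mu_for_pi(config$within_class_pi[2]),
               mu_for_pi(pi1_adj))
  n_panel <- length(labels)
  a <- matrix(0L, nrow = n_panel + n_failed + n_recombinant, ncol = n_sites)
  for (i in seq_len(n_panel)) {
    base <- switch(labels[i], `1a` = arch1a, `1b` = arch1, `2` = arch2)
    k <- stats::rpois(1, mu[i])
    if (k > 0) {
      flip <- sample(ex_i, min(k, ne))
      base[flip] <- 1L - base[flip]
    }
    a[i, ] <- base
  }
  hf <- rep(0.35, nrow(a))  # nominal heterozygosity of a successful cross
  if (n_failed > 0) {
    for (i in seq_len(n_failed)) a[n_panel + i, ] <- arch1
    hf[n_panel + seq_len(n_failed)] <- 0
    labels <- c(labels, rep("failed", n_failed))
  }
  if (n_recombinant > 0) {
    for (i in seq_len(n_recombinant)) {
      bp <- sample(mk_i[seq(nm %/% 4, 3 * nm %/% 4)], 1)
      chim <- ifelse(seq_len(n_sites) <= bp, arch1, arch2)
      a[n_panel + n_failed + i, ] <- chim
    }
    labels <- c(labels, rep("recombinant", n_recombinant))
  }
  ids <- sprintf("hap%02d", seq_len(nrow(a)))
  hm <- haplotype_matrix(sites, a, ids = ids, L = config$L,
                         het_fraction = hf)
  # site tables in position order (matrix constructor sorts, order here too)
  markers <- sites[mk_i, , drop = FALSE]
  markers$class1_allele <- arch1[mk_i]
  markers <- markers[order(markers$pos), , drop = FALSE]
  rownames(markers) <- NULL
  resistance <- sites[res_i, , drop = FALSE]
  resistance <- resistance[order(resistance$pos), , drop = FALSE]
  rownames(resistance) <- NULL
  truth <- list(class_labels = stats::setNames(labels, ids),
                resistance_sites = resistance,
                marker_sites = markers,
                founder_class_freqs = config$founder_class_freqs,
                seed = seed)
  list(haplotypes = hm, truth = truth)
}

# 3x3 genotype fitness matrix from per-class s and dominance h:
# w_ii = 1 + s_i, w_ij = 1 + h (s_i + s_j)
fitness_matrix <- function(s, h) {
  w <- 1 + h * outer(s, s, `+`)
  diag(w) <- 1 + s
  w
}

#' Simulate replicate Wright-Fisher haplotype-class trajectories
#'
#' Treats the three haplotype classes as alleles of a single locus (no
#' recombination within the window during the experiment). Each generation,
#' class frequencies are updated deterministically by co-dominant selection
#' (genotype fitness `w_ij = 1 + h (s_i + s_j)`, `w_ii = 1 + s_i`) and then
#' resampled by a multinomial draw of `2 Ne` haplotypes; `Ne = Inf` gives the
#' deterministic limit. Drift acts at the effective size, matching how the
#' inference consumes Ne; the census size only affects pool sampling.
#'
#' @param config A [sim_config()].
#' @param regime Regime name (an element of `names(config$class_s)`).
#' @param seed RNG seed (default derived from `config$seed` and the regime).
#' @return A `ClassPaths` object: list with `regime`, `generations` (0..T),
#'   `sampled` generations, `paths` (array `n_replicates x (T+1) x 3`), `Ne`,
#'   `s`.
#' @export
simulate_wf_trajectories <- function(config, regime = config$regimes[1],
                                     seed = derive_seed(config$seed, 2,
                                                        match(regime, config$regimes))) {
  s <- config$class_s[[regime]]
  ne <- config$effective_Ne[[regime]]
  gens <- config$sampled_generations[[regime]]
  tmax <- max(gens)
  w <- fitness_matrix(s, config$h)
  paths <- array(NA_real_,
                 dim = c(config$n_replicates, tmax + 1L, 3L),
                 dimnames = list(NULL, NULL, names(s)))
  for (r in seq_len(config$n_replicates)) {
    set.seed(derive_seed(seed, r))
    p <- as.numeric(config$founder_class_freqs)
    paths[r, 1L, ] <- p
    for (g in seq_len(tmax)) {
      wm <- as.numeric(w %*% p)
      pe <- p * wm / sum(p * wm)
      if (is.finite(ne[r])) {
        cnt <- stats::rmultinom(1, size = 2L * ne[r], prob = pe)
        p <- as.numeric(cnt) / (2 * ne[r])
      } else {
        p <- pe
      }
      paths[r, g + 1L, ] <- p
    }
  }
  structure(list(regime = regime, generations = 0:tmax, sampled = gens,
                 paths = paths, Ne = ne, s = s),
            class = "ClassPaths")
}

#' Simulate Pool-seq read counts from class-frequency paths
#'
#' For each site and sample the true alternative-allele frequency is the
#' class-frequency-weighted mean of the within-class allele frequencies of
#' the founder panel. Sequencing applies two sampling stages: a pool draw of
#' `2 * pool_size` haplotypes, then binomial read sampling at
#' Poisson(`mean_coverage`) depth. Zero-coverage site/samples are allowed.
#'
#' @param paths A `ClassPaths` from [simulate_wf_trajectories()].
#' @param founder Result of [simulate_founder()] (list with `haplotypes` and
#'   `truth`), or a `HaplotypeMatrix` plus `class_labels`.
#' @param config A [sim_config()].
#' @param seed RNG seed.
#' @param sites Optional index vector restricting output to a subset of
#'   founder sites (e.g. markers + resistance sites for speed).
#' @param class_labels Per-haplotype class labels; defaults to the founder
#'   truth labels.
#' @return An `AlleleCountTable` with one sample per (replicate, sampled
#'   generation), regime label attached.
#' @export
simulate_poolseq <- function(paths, founder, config,
                             seed = derive_seed(config$seed, 3,
                                                match(paths$regime, config$regimes)),
                             sites = NULL, class_labels = NULL) {
  hm <- if (inherits(founder, "HaplotypeMatrix")) founder else founder$haplotypes
  class_labels <- class_labels %||% founder$truth$class_labels
  lab <- class_labels[hm$ids]
  sj <- sites %||% seq_len(nrow(hm$sites))
  classes <- dimnames(paths$paths)[[3]]
  g_cs <- vapply(classes, function(cl) {
    colMeans(hm$alleles[lab == cl, sj, drop = FALSE] == 1L, na.rm = TRUE)
  }, numeric(length(sj)))  # site x class
  if (length(sj) == 1L) g_cs <- matrix(g_cs, nrow = 1)
  gens <- paths$sampled
  n_rep <- dim(paths$paths)[1]
  samp <- expand.grid(generation = gens, replicate = seq_len(n_rep))
  samp <- data.frame(replicate = samp$replicate, generation = samp$generation,
                     regime = paths$regime)
  n_site <- length(sj)
  counts <- array(0L, dim = c(nrow(samp), n_site, 6L),
                  dimnames = list(NULL, NULL, SYNC_NUC))
  n_hap_pool <- 2L * config$pool_size
  set.seed(seed)
  sites_df <- hm$sites[sj, , drop = FALSE]
  ri <- match(sites_df$ref, SYNC_NUC)
  ai <- match(sites_df$alt, SYNC_NUC)
  for (i in seq_len(nrow(samp))) {
    f <- paths$paths[samp$replicate[i], samp$generation[i] + 1L, ]
    p_true <- as.numeric(g_cs %*% f)
    p_pool <- stats::rbinom(n_site, n_hap_pool, p_true) / n_hap_pool
    cov <- stats::rpois(n_site, config$mean_coverage)
    altc <- stats::rbinom(n_site, cov, p_pool)
    counts[cbind(i, seq_len(n_site), ai)] <- altc
    counts[cbind(i, seq_len(n_site), ri)] <- cov - altc
  }
  allele_count_table(sites_df, samp, counts)
}

#' Simulate insecticide bioassay mortality
#'
#' Mortality probability follows a probit dose-response,
#' `Phi(slope * (log10(dose) - log10(ld50)))`; deaths are binomial per vial.
#' Dose 0 (control) has mortality probability 0 by convention.
#'
#' @param ld50 True LD50 (same dose units as `doses`, conventionally ug).
#' @param slope Probit slope per log10 dose unit (> 0).
#' @param doses Vector of doses; each is assayed in `n_vials` vials.
#' @param n_per_vial Flies exposed per vial (default 30).
#' @param n_vials Replicate vials per dose.
#' @param population,insecticide Labels carried into the records.
#' @param seed RNG seed (optional).
#' @return data.frame of dose-response records: `population`, `insecticide`,
#'   `dose`, `n_exposed`, `n_dead`.
#' @export
simulate_bioassay <- function(ld50, slope, doses, n_per_vial = 30L,
                              n_vials = 1L, population = "pop",
                              insecticide = "insecticide", seed = NULL) {
  if (ld50 <= 0 || slope <= 0) stopf("ld50 and slope must be positive")
  if (any(doses < 0)) stopf("doses must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  d <- rep(doses, each = n_vials)
  p <- ifelse(d == 0, 0, stats::pnorm(slope * (log10(d) - log10(ld50))))
  data.frame(population = population, insecticide = insecticide,
             dose = d, n_exposed = as.integer(n_per_vial),
             n_dead = stats::rbinom(length(d), n_per_vial, p),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic E&R experiment
#'
#' Runs [simulate_founder()], then for every regime
#' [simulate_wf_trajectories()] and [simulate_poolseq()]. The result carries
#' the full truth needed to regenerate the data and to score recovery.
#'
#' @param config A [sim_config()].
#' @param sites `"all"` or `"informative"`: simulate reads for every founder
#'   site or only for marker + resistance sites (faster; sufficient for the
#'   trajectory and selection analyses).
#' @return List with `founder`, per-regime `paths` and `poolseq`, and
#'   `config`.
#' @export
simulate_experiment <- function(config = sim_config(),
                                sites = c("all", "informative")) {
  sites <- match.arg(sites)
  founder <- simulate_founder(config)
  sj <- NULL
  if (sites == "informative") {
    keys <- c(site_key(founder$truth$marker_sites),
              site_key(founder$truth$resistance_sites))
    sj <- match(keys, site_key(founder$haplotypes$sites))
  }
  paths <- list()
  pools <- list()
  for (rg in config$regimes) {
    paths[[rg]] <- simulate_wf_trajectories(config, rg)
    pools[[rg]] <- simulate_poolseq(paths[[rg]], founder, config, sites = sj)
  }
  list(founder = founder, paths = paths, poolseq = pools, config = config)
}

#' Simulate independent neutral Pool-seq sites at two time points
#'
#' Generates unlinked neutrally drifting SNPs observed through the two-stage
#' Pool-seq sampling model, shared starting frequencies across replicates
#' (one founder), for calibrating the Ne estimator and the null distribution
#' of the CMH scans.
#'
#' @param n_sites Number of independent SNPs.
#' @param Ne Effective size (diploids) of every replicate.
#' @param t Generations between the two samples.
#' @param n_replicates Number of replicate populations.
#' @param p0 Starting frequencies (default `runif(n_sites, 0.2, 0.8)`).
#' @param pool_size Individuals pooled (haplotypes sampled = `2 * pool_size`).
#' @param mean_coverage Mean Poisson read coverage.
#' @param chrom Chromosome label for the synthetic sites.
#' @param seed RNG seed.
#' @return List with `table` (an `AlleleCountTable` with samples at
#'   generations 0 and `t` for each replicate) and `truth` (`p0`, realized
#'   per-replicate terminal frequencies).
#' @export
simulate_neutral_sites <- function(n_sites = 1000, Ne = 250, t = 15,
                                   n_replicates = 1, p0 = NULL,
                                   pool_size = 1000, mean_coverage = 80,
                                   chrom = "sim", seed = 1) {
  set.seed(seed)
  p0 <- p0 %||% stats::runif(n_sites, 0.2, 0.8)
  stopifnot(length(p0) == n_sites)
  sites <- data.frame(chrom = chrom, pos = seq_len(n_sites) * 100L,
                      ref = "A", alt = "C", stringsAsFactors = FALSE)
  samp <- expand.grid(generation = c(0L, as.integer(t)),
                      replicate = seq_len(n_replicates))
  samp <- data.frame(replicate = samp$replicate,
                     generation = samp$generation, regime = "sim")
  counts <- array(0L, dim = c(nrow(samp), n_sites, 6L),
                  dimnames = list(NULL, NULL, SYNC_NUC))
  nh <- 2L * pool_size
  pt <- matrix(NA_real_, n_replicates, n_sites)
  observe <- function(p) {
    pp <- stats::rbinom(n_sites, nh, p) / nh
    cov <- stats::rpois(n_sites, mean_coverage)
    alt <- stats::rbinom(n_sites, cov, pp)
    list(alt = alt, cov = cov)
  }
  for (r in seq_len(n_replicates)) {
    p <- p0
    for (g in seq_len(t)) p <- stats::rbinom(n_sites, 2 * Ne, p) / (2 * Ne)
    pt[r, ] <- p
    o0 <- observe(p0)
    o1 <- observe(p)
    i0 <- which(samp$replicate == r & samp$generation == 0L)
    i1 <- which(samp$replicate == r & samp$generation == t)
    counts[cbind(i0, seq_len(n_sites), 3L)] <- o0$alt      # C = alt
    counts[cbind(i0, seq_len(n_sites), 1L)] <- o0$cov - o0$alt
    counts[cbind(i1, seq_len(n_sites), 3L)] <- o1$alt
    counts[cbind(i1, seq_len(n_sites), 1L)] <- o1$cov - o1$alt
  }
  list(table = allele_count_table(sites, samp, counts),
       truth = list(p0 = p0, pt = pt, Ne = Ne, t = t,
                    pool_haplotypes = nh, mean_coverage = mean_coverage))
}
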