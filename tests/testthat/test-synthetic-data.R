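test_that("founder construction honors the class architecture", {
  cfg <- small_config(1)
  fd <- simulate_founder(cfg)
  hm <- fd$haplotypes
  truth <- fd$truth
  lab <- truth$class_labels[hm$ids]
  mk <- match(paste(truth$marker_sites$chrom, truth$marker_sites$pos),
              paste(hm$sites$chrom, hm$sites$pos))
  rs <- match(paste(truth$resistance_sites$chrom, truth$resistance_sites$pos),
              paste(hm$sites$chrom, hm$sites$pos))
  a1 <- hm$alleles[lab %in% c("1a", "1b"), mk, drop = FALSE]
  a2 <- hm$alleles[lab == "2", mk, drop = FALSE]
  # markers are fixed-different between the class archetypes by construction
  expect_true(all(apply(a1, 2, function(v) length(unique(v)) == 1)))
  expect_true(all(apply(a2, 2, function(v) length(unique(v)) == 1)))
  expect_true(all(a1[1, ] != a2[1, ]))
  # 1a carries the alternative allele at all three resistance sites; 1b/2 none
  expect_true(all(hm$alleles[lab == "1a", rs] == 1L))
  expect_true(all(hm$alleles[lab != "1a", rs] == 0L))
})

test_that("zero within-class diversity makes class-1 haplotypes identical off the triple", {
  cfg <- small_config(2, within_class_pi = c(class1 = 0, class2 = 0.008))
  fd <- simulate_founder(cfg)
  lab <- fd$truth$class_labels[fd$haplotypes$ids]
  a1b <- fd$haplotypes$alleles[lab == "1b", , drop = FALSE]
  expect_true(all(apply(a1b, 2, function(v) length(unique(v)) == 1)))
  a1a <- fd$haplotypes$alleles[lab == "1a", , drop = FALSE]
  expect_true(all(apply(a1a, 2, function(v) length(unique(v)) == 1)))
})

test_that("realized diversity matches the class targets (ratio about 20)", {
  ratios <- vapply(1:6, function(s) {
    fd <- simulate_founder(sim_config(seed = s))
    asg <- assign_classes(fd$haplotypes, fd$truth$resistance_sites)
    dv <- class_diversity(fd$haplotypes, asg)
    dv$pi[dv$class == "2"] / dv$pi[dv$class == "1"]
  }, numeric(1))
  expect_gt(mean(ratios), 15)
  expect_lt(mean(ratios), 26)
})

test_that("class frequencies always sum to one along every replicate path", {
  cfg <- small_config(5)
  for (rg in c("hot", "cold")) {
    pth <- simulate_wf_trajectories(cfg, rg)
    sums <- apply(pth$paths, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("neutral evolution at huge Ne keeps frequencies constant", {
  cfg <- small_config(
    6,
    class_s = list(hot = c(`1a` = 0, `1b` = 0, `2` = 0)),
    effective_Ne = list(hot = rep(1e8, 5)),
    sampled_generations = list(hot = c(0, 15, 37, 59)))
  pth <- simulate_wf_trajectories(cfg, "hot")
  dp <- apply(pth$paths, c(1, 3), function(v) max(abs(v - v[1])))
  expect_lt(max(dp), 2e-3)
})

test_that("with Ne = Inf and two classes the path equals the deterministic recursion", {
  s <- 0.07
  cfg <- small_config(
    7,
    founder_class_freqs = c(`1a` = 0.3, `1b` = 0.7, `2` = 0),
    class_s = list(hot = c(`1a` = s, `1b` = 0, `2` = 0)),
    effective_Ne = list(hot = rep(Inf, 5)),
    sampled_generations = list(hot = c(0, 15, 37, 59)))
  pth <- simulate_wf_trajectories(cfg, "hot")
  expect_equal(pth$paths[1, , "1a"], expected_trajectory(0.3, s, 0.5, 59),
               tolerance = 1e-12)
  # a class fixed at 0 is absorbing
  expect_true(all(pth$paths[, , "2"] == 0))
})

test_that("simulated drift matches the Wright-Fisher variance scaling", {
  ne <- 250
  t <- 20
  sim <- simulate_neutral_sites(n_sites = 4000, Ne = ne, t = t, seed = 31)
  p0 <- sim$truth$p0
  pt <- sim$truth$pt[1, ]
  ratio <- mean((pt - p0)^2 / (p0 * (1 - p0)))
  expected <- 1 - (1 - 1 / (2 * ne))^t
  expect_equal(ratio, expected, tolerance = 0.1)
  expect_lt(abs(mean(pt - p0)), 0.005)
})

test_that("mean simulated drop of the resistance class matches the deterministic drop", {
  # independent oracle: the three-allele selection recursion written out here
  cfg <- sim_config()
  s <- cfg$class_s$cold
  h <- cfg$h
  p <- as.numeric(cfg$founder_class_freqs)
  w <- 1 + h * outer(s, s, `+`)
  diag(w) <- 1 + s
  for (g in 1:51) {
    wm <- as.numeric(w %*% p)
    p <- p * wm / sum(p * wm)
  }
  det_drop <- cfg$founder_class_freqs[["1a"]] - p[1]
  drops <- vapply(1:200, function(seed) {
    pth <- simulate_wf_trajectories(sim_config(seed = seed), "cold")
    mean(pth$paths[, 1, "1a"] - pth$paths[, 52, "1a"])
  }, numeric(1))
  # finite-Ne drift adds an O(1/Ne) curvature term to the expected drop,
  # so the tolerance combines Monte-Carlo error with that scale
  mc_se <- stats::sd(drops) / sqrt(length(drops))
  expect_lt(abs(mean(drops) - det_drop), 4 * mc_se + 0.01)
})

test_that("identical seed and config give bit-identical sync output", {
  cfg <- small_config(9)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  e1 <- simulate_experiment(cfg, sites = "informative")
  e2 <- simulate_experiment(cfg, sites = "informative")
  write_sync(e1$poolseq$cold, f1)
  write_sync(e2$poolseq$cold, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(e1$paths$hot$paths, e2$paths$hot$paths)
})

test_that("pool-seq observation noise follows the two-stage sampling model", {
  # constant true frequency; drift switched off by an enormous Ne over t = 1
  p <- 0.3
  sim <- simulate_neutral_sites(n_sites = 10000, Ne = 5e8, t = 1,
                                p0 = rep(p, 10000), pool_size = 1000,
                                mean_coverage = 80, seed = 13)
  f <- act_alt_freq(sim$table)
  obs <- f[2, ]
  v_emp <- stats::var(obs[!is.na(obs)] - p)
  v_theory <- p * (1 - p) * (1 / 80 + 1 / 2000)
  expect_equal(v_emp, v_theory, tolerance = 0.1)
})

test_that("pool-seq sampling conserves fixed sites and the noise-free limit", {
  cfg <- small_config(11, mean_coverage = 2e6, pool_size = 2e6)
  exp <- simulate_experiment(cfg, sites = "informative")
  fd <- exp$founder
  pth <- exp$paths$cold
  tab <- exp$poolseq$cold
  # true alt frequency at a resistance site is the 1a class frequency
  rs <- match(paste(fd$truth$resistance_sites$chrom,
                    fd$truth$resistance_sites$pos)[1],
              paste(tab$sites$chrom, tab$sites$pos))
  f <- act_alt_freq(tab)
  for (i in seq_len(nrow(tab$samples))) {
    truef <- pth$paths[tab$samples$replicate[i],
                       tab$samples$generation[i] + 1, "1a"]
    expect_lt(abs(f[i, rs] - truef), 1e-2)
  }
  # a zero-frequency allele never yields alternative reads
  cfg0 <- small_config(
    12,
    founder_class_freqs = c(`1a` = 0, `1b` = 0.5, `2` = 0.5),
    within_class_pi = c(class1 = 0, class2 = 0))
  exp0 <- simulate_experiment(cfg0, sites = "informative")
  rs0 <- match(paste(exp0$founder$truth$resistance_sites$chrom,
                     exp0$founder$truth$resistance_sites$pos),
               paste(exp0$poolseq$cold$sites$chrom,
                     exp0$poolseq$cold$sites$pos))
  expect_true(all(act_allele_counts(exp0$poolseq$cold, "alt")[, rs0] == 0))
})

test_that("bioassay mortality follows the probit model", {
  # at dose = ld50 mortality is 1/2 in expectation
  rec <- simulate_bioassay(10, 2, rep(10, 400), n_per_vial = 30, seed = 21)
  expect_equal(mean(rec$n_dead / rec$n_exposed), 0.5, tolerance = 0.02)
  # a huge slope gives a step function around ld50
  rec2 <- simulate_bioassay(10, 1e6, c(9, 11), n_per_vial = 50, n_vials = 4,
                            seed = 22)
  expect_true(all(rec2$n_dead[rec2$dose < 10] == 0))
  expect_true(all(rec2$n_dead[rec2$dose > 10] == 50))
  # dose 0 is a control with zero mortality by convention
  rec3 <- simulate_bioassay(10, 2, c(0, 10), n_vials = 10, seed = 23)
  expect_true(all(rec3$n_dead[rec3$dose == 0] == 0))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(founder_class_freqs = c(`1a` = 0.6, `1b` = 0.25,
                                                  `2` = 0.2)),
               "sum to 1")
  expect_error(sim_config(class_s = list(hot = c(`1a` = -1.2, `1b` = 0,
                                                 `2` = 0))),
               "fitness")
  expect_error(sim_config(sampled_generations = list(
    hot = c(5, 15), cold = c(0, 11))), "start at 0")
  expect_error(sim_config(n_marker_snps = 2e5), "configuration error")
})
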