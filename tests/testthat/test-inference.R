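test_that("the deterministic trajectory behaves at the boundaries", {
  expect_equal(expected_trajectory(0.37, 0, 0.5, 25), rep(0.37, 26))
  expect_equal(expected_trajectory(0, 0.2, 0.5, 10), rep(0, 11))
  expect_equal(expected_trajectory(1, -0.2, 0.5, 10), rep(1, 11))
  p <- expected_trajectory(0.01, 0.1, 0.5, 300)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))  # monotone for fixed-sign s
  pn <- expected_trajectory(0.99, -0.1, 0.5, 300)
  expect_true(all(diff(pn) <= 0))
  expect_error(expected_trajectory(1.2, 0, 0.5, 5), "p0")
  expect_error(expected_trajectory(0.5, -1.5, 0.5, 5), "1 \\+ s")
})

test_that("for small s the logit change approximates (s/2) t under co-dominance", {
  p <- expected_trajectory(0.5, 0.01, 0.5, 50)
  ratio <- (qlogis(p[51]) - qlogis(p[1])) / (0.01 / 2 * 50)
  expect_equal(ratio, 1, tolerance = 0.02)
})

test_that("selection fitting inverts noise-free deterministic trajectories", {
  for (case in list(c(0.5, 0.05), c(0.3, -0.08), c(0.7, 0.12))) {
    p0 <- case[1]
    s <- case[2]
    path <- expected_trajectory(p0, s, 0.5, 50)
    fit <- estimate_s(data.frame(generation = 0:50, frequency = path))
    expect_lt(abs(fit$s - s), 1e-6)
    expect_equal(fit$p0, p0, tolerance = 1e-4)
    # sparse sampling at the experimental generations also inverts
    g <- c(0, 11, 21, 31, 41, 51)
    path2 <- expected_trajectory(p0, s, 0.5, 51)
    fit2 <- estimate_s(data.frame(generation = g, frequency = path2[g + 1]))
    expect_lt(abs(fit2$s - s), 1e-6)
  }
})

test_that("a constant trajectory is fitted as neutral", {
  fit <- estimate_s(data.frame(generation = c(0, 11, 21, 31, 41),
                               frequency = rep(0.4, 5)))
  expect_equal(fit$s, 0, tolerance = 1e-8)
  expect_equal(fit$p0, 0.4)
})

test_that("relabeling the focal allele maps s to its exact conjugate", {
  # under h = 1/2 the complementary frequency follows the same recursion
  # with s' = -s/(1+s); for small s this is the plain sign flip
  s <- 0.05
  path <- expected_trajectory(0.5, s, 0.5, 50)
  fit <- estimate_s(data.frame(generation = 0:50, frequency = 1 - path))
  expect_lt(abs(fit$s - (-s / (1 + s))), 1e-6)
  s2 <- 1e-4
  path2 <- expected_trajectory(0.5, s2, 0.5, 50)
  fit2 <- estimate_s(data.frame(generation = 0:50, frequency = 1 - path2))
  expect_lt(abs(fit2$s + s2), 1e-6)
})

test_that("degenerate trajectories are rejected with a clear message", {
  expect_error(estimate_s(data.frame(generation = c(0, 10),
                                     frequency = c(0, 0))),
               "no information")
  expect_error(estimate_s(data.frame(generation = 0, frequency = 0.5)),
               "2 time points")
})

test_that("the joint three-class fit recovers pairwise coefficients exactly", {
  cfg <- sim_config(seed = 1,
                    effective_Ne = list(hot = rep(Inf, 5),
                                        cold = rep(Inf, 5)))
  for (rg in c("hot", "cold")) {
    pth <- simulate_wf_trajectories(cfg, rg)
    gens <- pth$sampled
    tr <- do.call(rbind, lapply(c("1a", "1b", "2"), function(cl) {
      data.frame(generation = gens, class = cl,
                 frequency = pth$paths[1, gens + 1, cl])
    }))
    jf <- estimate_s_joint(tr)
    expect_lt(abs(jf$s[["1a"]] - cfg$class_s[[rg]][["1a"]]), 1e-4)
    expect_lt(abs(jf$s[["2"]] - cfg$class_s[[rg]][["2"]]), 1e-4)
    expect_lt(max(abs(unname(jf$p0) -
                        as.numeric(cfg$founder_class_freqs))), 1e-4)
  }
})

test_that("no frequency change means F = 0 and an infinite flagged Ne", {
  x <- c(0.2, 0.5, 0.8)
  est <- suppressWarnings(estimate_ne(x, x, t = 10, S0 = 2000, St = 2000,
                                      R0 = 80, Rt = 80))
  expect_equal(est$ne, Inf)
  expect_false(is.null(est$flag))
  expect_error(estimate_ne(c(0, 1), c(0, 1), t = 10, S0 = 2000, St = 2000,
                           R0 = 80, Rt = 80),
               "no polymorphic")
})

test_that("Ne estimates are consistent when the time span doubles", {
  med <- vapply(c(10, 20), function(t) {
    nes <- vapply(1:8, function(seed) {
      sim <- simulate_neutral_sites(n_sites = 1500, Ne = 250, t = t,
                                    seed = 100 + seed)
      f <- act_alt_freq(sim$table)
      cov <- act_coverage(sim$table)
      estimate_ne(f[1, ], f[2, ], t = t, S0 = 2000, St = 2000,
                  R0 = cov[1, ], Rt = cov[2, ])$ne
    }, numeric(1))
    median(nes)
  }, numeric(1))
  expect_equal(med[1], med[2], tolerance = 0.2)
  expect_equal(med[1], 250, tolerance = 0.25)
})

test_that("the classic CMH statistic matches the textbook formula and mantelhaen.test", {
  # single replicate [[60,40],[40,60]]: hand-computed score
  one <- data.frame(replicate = 1L, generation = c(0L, 51L), regime = "sim")
  tab <- make_act(rbind(60L, 40L), rbind(100L, 100L), one)
  scan <- cmh_scan(tab, mode = "classic")
  a <- 60; n0 <- 100; n1 <- 100; N <- 200; m1 <- 100; m2 <- 100
  stat_hand <- (a - n0 * m1 / N)^2 / (n0 * n1 * m1 * m2 / (N^2 * (N - 1)))
  expect_equal(scan$statistic, stat_hand, tolerance = 1e-12)
  # K = 3 replicates against stats::mantelhaen.test (continuity off)
  set.seed(5)
  alt0 <- c(55L, 48L, 61L); alt1 <- c(30L, 41L, 25L)
  cov0 <- c(90L, 85L, 100L); cov1 <- c(80L, 95L, 70L)
  samples <- data.frame(replicate = rep(1:3, each = 2),
                        generation = rep(c(0L, 51L), 3), regime = "sim")
  tab3 <- make_act(matrix(c(alt0[1], alt1[1], alt0[2], alt1[2],
                            alt0[3], alt1[3]), 6, 1),
                   matrix(c(cov0[1], cov1[1], cov0[2], cov1[2],
                            cov0[3], cov1[3]), 6, 1),
                   samples)
  scan3 <- cmh_scan(tab3, mode = "classic")
  arr <- array(0, c(2, 2, 3))
  for (k in 1:3) {
    arr[, , k] <- rbind(c(alt0[k], alt1[k]),
                        c(cov0[k] - alt0[k], cov1[k] - alt1[k]))
  }
  mh <- stats::mantelhaen.test(arr, correct = FALSE)
  expect_equal(scan3$statistic, unname(mh$statistic), tolerance = 1e-10)
  expect_equal(scan3$p, unname(mh$p.value), tolerance = 1e-10)
})

test_that("identical counts in all replicates give statistic 0 and p = 1", {
  samples <- data.frame(replicate = rep(1:2, each = 2),
                        generation = rep(c(0L, 51L), 2), regime = "sim")
  tab <- make_act(matrix(30L, 4, 2), matrix(100L, 4, 2), samples)
  for (mode in c("classic", "adjusted")) {
    scan <- cmh_scan(tab, ne = c(250, 250), mode = mode)
    expect_equal(scan$statistic, c(0, 0))
    expect_equal(scan$p, c(1, 1))
  }
})

test_that("sites without coverage in a replicate are NA with a reason", {
  samples <- data.frame(replicate = rep(1:2, each = 2),
                        generation = rep(c(0L, 51L), 2), regime = "sim")
  alt <- matrix(c(30L, 10L, 0L, 5L), 4, 1)
  cov <- matrix(c(100L, 100L, 0L, 100L), 4, 1)
  tab <- make_act(alt, cov, samples)
  scan <- cmh_scan(tab, ne = c(250, 250))
  expect_true(is.na(scan$statistic))
  expect_match(scan$na_reason, "coverage")
})

test_that("adjusted CMH p-values are uniform under the neutral null", {
  sim <- simulate_neutral_sites(n_sites = 1000, Ne = 250, t = 51,
                                n_replicates = 5, seed = 7)
  adj <- cmh_scan(sim$table, ne = rep(250, 5), pool_size = 1000)
  p <- adj$p[!is.na(adj$p)]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("class-1 markers outrank the resistance sites in the scan", {
  # class 2 is fittest, so sites shared by 1a + 1b change more than the
  # resistance sites restricted to 1a
  cfg <- sim_config(seed = 11)
  exp <- simulate_experiment(cfg, sites = "informative")
  fd <- exp$founder
  for (rg in c("hot", "cold")) {
    scan <- cmh_scan(exp$poolseq[[rg]], ne = cfg$effective_Ne[[rg]])
    keys <- paste(scan$chrom, scan$pos)
    pm <- scan$p[keys %in% paste(fd$truth$marker_sites$chrom,
                                 fd$truth$marker_sites$pos)]
    pr <- scan$p[keys %in% paste(fd$truth$resistance_sites$chrom,
                                 fd$truth$resistance_sites$pos)]
    expect_gt(median(-log10(pm), na.rm = TRUE),
              median(-log10(pr), na.rm = TRUE))
  }
})

test_that("the resistance-cost contrast is plain per-replicate arithmetic", {
  fits <- data.frame(replicate = c(1, 1, 2, 2),
                     class = c("1a", "1b", "1a", "1b"),
                     s = c(-0.02, 0.01, -0.04, -0.04))
  rc <- resistance_cost(fits)
  expect_equal(rc$contrast, c(-0.03, 0))
  expect_equal(attr(rc, "mean"), -0.015)
  expect_equal(attr(rc, "sem"), sd(c(-0.03, 0)) / sqrt(2))
  # a replicate missing one class is dropped with a warning
  expect_warning(rc2 <- resistance_cost(fits[-4, ]), "missing")
  expect_equal(rc2$replicate, 1)
})
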