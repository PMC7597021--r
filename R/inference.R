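#' Deterministic co-dominant Wright-Fisher allele-frequency trajectory
#'
#' Iterates the standard diploid selection recursion for an allele with
#' fitness `1 + s` (homozygote), `1 + h s` (heterozygote) against a baseline
#' of 1:
#' `p' = p (p (1+s) + q (1+h s)) / (p^2 (1+s) + 2 p q (1+h s) + q^2)`.
#'
#' @param p0 Starting frequency in `[0, 1]`.
#' @param s Selection coefficient (`1 + s > 0`).
#' @param h Dominance coefficient (`1 + h s > 0`); 0.5 = co-dominance.
#' @param t Number of generations.
#' @return Numeric vector of length `t + 1` (generations 0..t).
#' @export
expected_trajectory <- function(p0, s, h = 0.5, t) {
  if (p0 < 0 || p0 > 1) stopf("p0 must lie in [0, 1]")
  if (1 + s <= 0 || 1 + h * s <= 0) stopf("need 1 + s > 0 and 1 + h*s > 0")
  p <- numeric(t + 1)
  p[1] <- p0
  if (t == 0) return(p)
  for (g in seq_len(t)) {
    pp <- p[g]
    q <- 1 - pp
    wbar <- pp^2 * (1 + s) + 2 * pp * q * (1 + h * s) + q^2
    p[g + 1] <- pp * (pp * (1 + s) + q * (1 + h * s)) / wbar
  }
  p
}

#' Temporal effective population size from allele-frequency change
#'
#' Per polymorphic site, the standardized squared frequency change is
#' `F_c = (x - y)^2 / (z (1 - z))` with `z = (x + y) / 2`. The average over
#' sites is corrected for the two-stage Pool-seq sampling noise at each time
#' point (pool draw of `S` haplotypes and read draw at coverage `R`:
#' `1/S + 1/R - 1/(S R)` per time point), and inverted through the drift
#' expectation: `Ne = -t / (2 ln(1 - F_corr))` (diploids). A non-positive
#' corrected F yields `Ne = +Inf` with a flag.
#'
#' @param x,y Observed allele frequencies at the first and second time point
#'   (vectors over sites).
#' @param t Generations between the samples (`>= 1`).
#' @param S0,St Haplotypes sampled into the pool at each time point
#'   (2 x individuals).
#' @param R0,Rt Read coverages at each time point (scalar or per-site).
#' @param replicate Optional replicate id carried into the result.
#' @return An `NeEstimate`: list with `ne`, `n_snps`, `t`, `F_raw`, `F_corr`,
#'   `flag`, `method`, `replicate`.
#' @export
estimate_ne <- function(x, y, t, S0, St, R0, Rt, replicate = NA) {
  stopifnot(length(x) == length(y), t >= 1)
  R0 <- rep_len(R0, length(x))
  Rt <- rep_len(Rt, length(x))
  z <- (x + y) / 2
  keep <- !is.na(z) & z > 0 & z < 1 & R0 > 0 & Rt > 0
  if (!any(keep)) stopf("no polymorphic site with coverage; Ne undefined")
  if (sum(keep) < 50) {
    warnf("only %d polymorphic sites; Ne estimate will be noisy", sum(keep))
  }
  fc <- (x[keep] - y[keep])^2 / (z[keep] * (1 - z[keep]))
  corr <- (1 / S0 + 1 / R0[keep] - 1 / (S0 * R0[keep])) +
    (1 / St + 1 / Rt[keep] - 1 / (St * Rt[keep]))
  f_raw <- mean(fc)
  f_corr <- f_raw - mean(corr)
  flag <- NULL
  if (f_corr <= 0) {
    ne <- Inf
    flag <- "non-positive corrected F; drift signal below sampling noise"
  } else {
    ne <- -t / (2 * log(1 - f_corr))
  }
  structure(list(ne = ne, n_snps = sum(keep), t = t, F_raw = f_raw,
                 F_corr = f_corr, flag = flag, method = "Fc-twostage",
                 replicate = replicate),
            class = "NeEstimate")
}

#' @export
print.NeEstimate <- function(x, ...) {
  cat(sprintf("Ne = %.4g (replicate %s, %d SNPs, t = %d generations, %s)\n",
              x$ne, x$replicate, x$n_snps, x$t, x$method))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

# residual sum of squares of the deterministic trajectory against observed
# frequencies; gens are 0-based generation indices
traj_rss <- function(f, gens, p0, s, h) {
  path <- expected_trajectory(p0, s, h, max(gens))
  sum((f - path[gens + 1L])^2)
}

# best p0 (and rss) for a fixed s
profile_p0 <- function(f, gens, s, h, eps) {
  o <- stats::optimize(function(lp) traj_rss(f, gens, stats::plogis(lp), s, h),
                       interval = stats::qlogis(c(eps, 1 - eps)),
                       tol = 1e-10)
  list(p0 = stats::plogis(o$minimum), rss = o$objective)
}

#' Fit a co-dominant Wright-Fisher selection coefficient to a trajectory
#'
#' Finds the selection coefficient `s` (and starting frequency `p0`)
#' minimizing the sum of squared deviations between the observed frequencies
#' and the deterministic trajectory [expected_trajectory()], with `s` bounded
#' in `[-0.5, 0.5]`. The initial value comes from the slope of the
#' logit-frequency regression on generation divided by `h`. Boundary
#' frequencies (0 or 1) are replaced by the pseudo-frequency
#' `1 / (2 * pool_haplotypes)`. Drift is not modeled in the objective; `Ne`
#' is carried for reporting. Ties are resolved toward the smallest `|s|`: a
#' neutral fit whose residual sum of squares matches the optimum within
#' 1e-12 is preferred.
#'
#' @param traj data.frame with columns `generation` (0-based integers) and
#'   `frequency`, e.g. from [class_trajectory()].
#' @param Ne Effective population size used alongside this fit (reported).
#' @param h Dominance coefficient (fixed at 0.5, co-dominance, by default).
#' @param pool_haplotypes Haplotypes per Pool-seq sample, for the boundary
#'   pseudo-frequency (default 2000 = 2 x 1000 flies).
#' @param endpoints_only Use only the first and last time point.
#' @param class_label,replicate Metadata carried into the fit.
#' @return A `SelectionFit`: list with `s`, `p0`, `h`, `Ne`, `rss`,
#'   `generations`, `n_points`, `convergence`, `class_label`, `replicate`.
#' @export
estimate_s <- function(traj, Ne = NA_real_, h = 0.5, pool_haplotypes = 2000,
                       endpoints_only = FALSE, class_label = NA_character_,
                       replicate = NA) {
  traj <- as.data.frame(traj)
  stopifnot(all(c("generation", "frequency") %in% names(traj)))
  traj <- traj[order(traj$generation), , drop = FALSE]
  if (endpoints_only && nrow(traj) > 2) {
    traj <- traj[c(1, nrow(traj)), , drop = FALSE]
  }
  gens <- as.integer(traj$generation)
  f <- as.numeric(traj$frequency)
  if (length(f) < 2) stopf("need at least 2 time points")
  if (any(gens < 0)) stopf("generations must be >= 0")
  if (all(f <= 0) || all(f >= 1)) {
    stopf("no information: trajectory fixed at %d for all points",
          as.integer(f[1] >= 1))
  }
  eps <- 1 / (2 * pool_haplotypes)
  f <- clamp(f, eps, 1 - eps)
  # initial s from the logit slope
  lf <- stats::qlogis(f)
  gc <- gens - mean(gens)
  slope <- if (sum(gc^2) > 0) sum(gc * (lf - mean(lf))) / sum(gc^2) else 0
  s_init <- clamp(slope / max(h, 0.25), -0.45, 0.45)
  obj <- function(par) {
    traj_rss(f, gens, stats::plogis(par[2]), clamp(par[1], -0.5, 0.5), h)
  }
  fit <- stats::optim(c(s_init, stats::qlogis(clamp(f[1], eps, 1 - eps))),
                      obj, method = "L-BFGS-B",
                      lower = c(-0.5, stats::qlogis(eps)),
                      upper = c(0.5, stats::qlogis(1 - eps)),
                      control = list(factr = 10))
  # 1-D polish of s with p0 profiled out, for tight tolerance on s
  lo <- max(-0.5, fit$par[1] - 0.02)
  hi <- min(0.5, fit$par[1] + 0.02)
  pol <- stats::optimize(function(s) profile_p0(f, gens, s, h, eps)$rss,
                         interval = c(lo, hi), tol = 1e-10)
  if (pol$objective <= fit$value) {
    s_hat <- pol$minimum
    pp <- profile_p0(f, gens, s_hat, h, eps)
    p0_hat <- pp$p0
    rss <- pp$rss
  } else {
    s_hat <- fit$par[1]
    p0_hat <- stats::plogis(fit$par[2])
    rss <- fit$value
  }
  # tie-break toward neutrality
  rss0 <- traj_rss(f, gens, mean(f), 0, h)
  if (rss0 <= rss + 1e-12) {
    s_hat <- 0
    p0_hat <- mean(f)
    rss <- rss0
  }
  structure(list(s = s_hat, p0 = p0_hat, h = h, Ne = Ne, rss = rss,
                 generations = gens, n_points = length(f),
                 convergence = fit$convergence, class_label = class_label,
                 replicate = replicate),
            class = "SelectionFit")
}

#' @export
print.SelectionFit <- function(x, ...) {
  cat(sprintf("s = %+.5f (class %s, replicate %s, h = %g, p0 = %.4f, rss = %.3g, %d points)\n",
              x$s, x$class_label, x$replicate, x$h, x$p0, x$rss, x$n_points))
  invisible(x)
}

#' Joint three-class co-dominant Wright-Fisher selection fit
#'
#' Fits the deterministic three-allele diploid selection recursion (genotype
#' fitness `w_ij = 1 + h (s_i + s_j)`, `w_ii = 1 + s_i`) to the class
#' frequency trajectories of one replicate by least squares over all classes
#' and time points. Class 1b is the fitness baseline (`s_1b = 0`), so the
#' fitted `s_1a` *is* the 1a-1b contrast and `s_2` the class-2 advantage
#' over 1b. The founder composition is co-estimated on the simplex.
#'
#' Fitting each class marginally against the rest with the two-allele
#' recursion and subtracting the fits leaves an interaction bias when a
#' third class sweeps (the background fitness felt by 1a and 1b differs);
#' the joint fit removes it and is the recommended estimator for
#' three-class experiments.
#'
#' @param traj data.frame for one replicate with columns `generation`,
#'   `class` (1a/1b/2) and `frequency` (e.g. a one-replicate subset of a
#'   `ClassTrajectorySet`).
#' @param Ne Effective size carried into the fits (reporting only).
#' @param h Dominance coefficient (default 0.5, co-dominance).
#' @param s_bound Bound on each selection coefficient.
#' @param replicate Metadata label.
#' @return List of class `JointSelectionFit` with elements `s` (named
#'   vector, 1b = 0), `p0` (founder simplex), `h`, `Ne`, `rss`,
#'   `convergence`, `replicate`.
#' @export
estimate_s_joint <- function(traj, Ne = NA_real_, h = 0.5, s_bound = 0.5,
                             replicate = NA) {
  traj <- as.data.frame(traj)
  classes <- c("1a", "1b", "2")
  gens <- sort(unique(traj$generation))
  if (length(gens) < 2) stopf("need at least 2 time points")
  fmat <- sapply(classes, function(cl) {
    d <- traj[traj$class == cl, , drop = FALSE]
    d$frequency[match(gens, d$generation)]
  })
  if (anyNA(fmat)) stopf("every class needs a frequency at every generation")
  tmax <- max(gens)
  path_rss <- function(s1a, s2, p0) {
    w <- fitness_matrix(c(s1a, 0, s2), h)
    p <- p0
    rss <- sum((fmat[1, ] - p)^2)
    gi <- 2L
    for (g in seq_len(tmax)) {
      wm <- as.numeric(w %*% p)
      p <- p * wm / sum(p * wm)
      if (gi <= length(gens) && gens[gi] == g) {
        rss <- rss + sum((fmat[gi, ] - p)^2)
        gi <- gi + 1L
      }
    }
    rss
  }
  # parameters: s_1a, s_2, and the founder simplex via two logits
  unpack_p0 <- function(par) {
    e <- exp(c(par[3], par[4], 0))
    e / sum(e)
  }
  obj <- function(par) path_rss(par[1], par[2], unpack_p0(par))
  f0 <- pmax(fmat[1, ], 1e-4)
  init <- c(0, 0, log(f0[1] / f0[3]), log(f0[2] / f0[3]))
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(-s_bound, -s_bound, -12, -12),
                      upper = c(s_bound, s_bound, 12, 12),
                      control = list(maxit = 500, factr = 10))
  s <- c(`1a` = fit$par[1], `1b` = 0, `2` = fit$par[2])
  structure(list(s = s, p0 = stats::setNames(unpack_p0(fit$par), classes),
                 h = h, Ne = Ne, rss = fit$value,
                 convergence = fit$convergence, replicate = replicate),
            class = "JointSelectionFit")
}

#' @export
print.JointSelectionFit <- function(x, ...) {
  cat(sprintf("joint WF fit (replicate %s): s_1a = %+.4f, s_1b = 0, s_2 = %+.4f (h = %g, rss = %.3g)\n",
              x$replicate, x$s["1a"], x$s["2"], x$h, x$rss))
  invisible(x)
}

#' Fit selection coefficients for every replicate and haplotype class
#'
#' Convenience wrapper applying [estimate_s()] to each (replicate, class)
#' trajectory of a `ClassTrajectorySet`.
#'
#' @param traj A `ClassTrajectorySet` from [class_frequencies()].
#' @param ne Per-replicate Ne values (vector, recycled/indexed by replicate).
#' @param classes Class labels to fit (default all three).
#' @param method `"joint"` (default; one three-allele fit per replicate, see
#'   [estimate_s_joint()]) or `"marginal"` (one [estimate_s()] fit per class
#'   trajectory against the rest).
#' @param ... Passed to the underlying fit function.
#' @return data.frame with columns `replicate`, `class`, `s`, `p0`, `rss`,
#'   `Ne`; fit objects in `attr(, "fits")`.
#' @export
fit_all_classes <- function(traj, ne = NA_real_,
                            classes = c("1a", "1b", "2"),
                            method = c("joint", "marginal"), ...) {
  method <- match.arg(method)
  reps <- unique(traj$replicate)
  ne <- rep_len(ne, length(reps))
  rows <- list()
  fits <- list()
  for (i in seq_along(reps)) {
    if (method == "joint") {
      ft <- estimate_s_joint(traj[traj$replicate == reps[i], , drop = FALSE],
                             Ne = ne[i], replicate = reps[i], ...)
      fits[[as.character(reps[i])]] <- ft
      for (cl in classes) {
        rows[[paste(reps[i], cl)]] <-
          data.frame(replicate = reps[i], class = cl, s = unname(ft$s[cl]),
                     p0 = unname(ft$p0[cl]), rss = ft$rss, Ne = ne[i],
                     stringsAsFactors = FALSE)
      }
    } else {
      for (cl in classes) {
        ft <- estimate_s(class_trajectory(traj, reps[i], cl), Ne = ne[i],
                         class_label = cl, replicate = reps[i], ...)
        fits[[paste(reps[i], cl)]] <- ft
        rows[[paste(reps[i], cl)]] <-
          data.frame(replicate = reps[i], class = cl, s = ft$s, p0 = ft$p0,
                     rss = ft$rss, Ne = ne[i], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Per-replicate selection-coefficient contrast s(1a) - s(1b)
#'
#' The fitness cost of the three linked resistance mutations is measured as
#' the difference between the selection coefficient of class 1a (which
#' carries them) and its near-identical sister class 1b (which does not),
#' per replicate, summarized by the mean and standard error across
#' replicates.
#'
#' @param fits data.frame with columns `replicate`, `class`, `s` (e.g. from
#'   [fit_all_classes()]), containing classes `1a` and `1b`.
#' @return data.frame with columns `replicate`, `s_1a`, `s_1b`, `contrast`;
#'   attributes `mean` and `sem`. Replicates missing either fit are dropped
#'   with a warning.
#' @export
resistance_cost <- function(fits) {
  f1a <- fits[fits$class == "1a", c("replicate", "s")]
  f1b <- fits[fits$class == "1b", c("replicate", "s")]
  reps <- union(f1a$replicate, f1b$replicate)
  i1 <- match(reps, f1a$replicate)
  i2 <- match(reps, f1b$replicate)
  miss <- is.na(i1) | is.na(i2)
  if (any(miss)) {
    warnf("replicate(s) %s missing a 1a or 1b fit; excluded",
          paste(reps[miss], collapse = ", "))
  }
  reps <- reps[!miss]
  out <- data.frame(replicate = reps,
                    s_1a = f1a$s[i1[!miss]],
                    s_1b = f1b$s[i2[!miss]])
  out$contrast <- out$s_1a - out$s_1b
  attr(out, "mean") <- mean(out$contrast)
  attr(out, "sem") <- if (nrow(out) > 1) {
    stats::sd(out$contrast) / sqrt(nrow(out))
  } else {
    NA_real_
  }
  class(out) <- c("ContrastTable", "data.frame")
  out
}

#' @export
print.ContrastTable <- function(x, ...) {
  print.data.frame(x, ...)
  cat(sprintf("mean s(1a) - s(1b) = %+.4f (SEM %.4f, %d replicates)\n",
              attr(x, "mean"), attr(x, "sem"), nrow(x)))
  invisible(x)
}

#' Cochran-Mantel-Haenszel scan over replicated allele-frequency change
#'
#' Tests, per site, whether allele counts changed between a first and a last
#' generation consistently across replicates. Two modes:
#'
#' * `classic`: the standard CMH chi-squared statistic (1 df, no continuity
#'   correction) over K replicate 2x2 tables of (allele x generation) read
#'   counts. Pool-seq reads are treated as independent allele draws, so
#'   drift between the time points inflates the statistic.
#' * `adjusted`: a drift-aware score statistic on the per-replicate
#'   frequency differences, `(sum_k (x_k - y_k))^2 / sum_k Var_k` with
#'   `Var_k = z(1-z) * [(1 - (1 - 1/(2 Ne_k))^t) + 1/R0 + 1/Rt + 1/S0 +
#'   1/St]`, which adds the Wright-Fisher drift variance and both Pool-seq
#'   sampling stages to the null variance; p-values from chi-squared(1).
#'
#' @param x An `AlleleCountTable` whose samples include the two generations
#'   for every replicate.
#' @param gen_pair Length-2 vector `(first, last)` generation; default the
#'   minimum and maximum generation present.
#' @param ne Per-replicate effective sizes (diploids); required for
#'   `adjusted`.
#' @param pool_size Individuals per pool (haplotypes sampled = 2x this).
#' @param mode `"adjusted"` (default) or `"classic"`.
#' @return A `CmhResult` data.frame: `chrom`, `pos`, `statistic`, `df`, `p`,
#'   `mode`, `na_reason`. Sites with zero coverage in any replicate/time
#'   point are `NA` with a reason.
#' @export
cmh_scan <- function(x, gen_pair = NULL, ne = NULL, pool_size = 1000,
                     mode = c("adjusted", "classic")) {
  mode <- match.arg(mode)
  gens <- x$samples$generation
  gen_pair <- gen_pair %||% c(min(gens), max(gens))
  reps <- unique(x$samples$replicate)
  k <- length(reps)
  if (mode == "adjusted") {
    if (is.null(ne)) stopf("adjusted mode requires per-replicate ne")
    ne <- rep_len(ne, k)
  }
  i0 <- match(paste(reps, gen_pair[1]), paste(x$samples$replicate, gens))
  i1 <- match(paste(reps, gen_pair[2]), paste(x$samples$replicate, gens))
  if (anyNA(i0) || anyNA(i1)) {
    stopf("every replicate needs samples at generations %d and %d",
          gen_pair[1], gen_pair[2])
  }
  alt <- act_allele_counts(x, "alt")
  ref <- act_allele_counts(x, "ref")
  a0 <- alt[i0, , drop = FALSE]; r0 <- ref[i0, , drop = FALSE]
  a1 <- alt[i1, , drop = FALSE]; r1 <- ref[i1, , drop = FALSE]
  c0 <- a0 + r0
  c1 <- a1 + r1
  n_site <- nrow(x$sites)
  stat <- rep(NA_real_, n_site)
  reason <- rep(NA_character_, n_site)
  no_cov <- apply(c0 == 0, 2, any) | apply(c1 == 0, 2, any)
  reason[no_cov] <- "insufficient coverage in at least one replicate"
  ok <- !no_cov
  if (mode == "classic") {
    n <- c0 + c1
    ea <- c0 * (a0 + a1) / n
    va <- c0 * c1 * (a0 + a1) * (r0 + r1) / (n^2 * (n - 1))
    va[n <= 1] <- 0
    num <- colSums(a0 - ea)^2
    den <- colSums(va)
    mono <- ok & den == 0
    reason[mono] <- "monomorphic in all replicates"
    use <- ok & den > 0
    stat[use] <- num[use] / den[use]
  } else {
    xk <- a0 / c0
    yk <- a1 / c1
    z <- (xk + yk) / 2
    t_gen <- gen_pair[2] - gen_pair[1]
    drift <- 1 - (1 - 1 / (2 * ne))^t_gen
    s_hap <- 2 * pool_size
    vk <- z * (1 - z) *
      (drift + 1 / c0 + 1 / c1 + 2 / s_hap)
    num <- colSums(xk - yk)^2
    den <- colSums(vk)
    mono <- ok & den == 0
    reason[mono] <- "monomorphic in all replicates"
    use <- ok & den > 0
    stat[use] <- num[use] / den[use]
  }
  out <- data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
                    statistic = stat, df = 1L,
                    p = stats::pchisq(stat, 1, lower.tail = FALSE),
                    mode = mode, na_reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("CmhResult", "data.frame")
  out
}
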