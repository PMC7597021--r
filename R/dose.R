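# binomial probit log-likelihood on dose-response records
probit_loglik <- function(records, a, b) {
  d <- records[records$dose > 0, , drop = FALSE]
  p <- stats::pnorm(a + b * log10(d$dose))
  p <- clamp(p, 1e-12, 1 - 1e-12)
  sum(d$n_dead * log(p) + (d$n_exposed - d$n_dead) * log(1 - p))
}

#' Probit dose-response fit and LD50 estimation
#'
#' Maximizes the binomial likelihood of mortality =
#' `Phi(a + b * log10(dose))` over the positive-dose records and reports
#' `LD50 = 10^(-a/b)` with a delta-method confidence interval on the log10
#' dose scale. Dose-0 (control) records are excluded from the fit (log10
#' undefined); with `control_correction = TRUE` observed mortalities are
#' first Abbott-corrected for the mean control mortality (off by default). A
#' Pearson heterogeneity chi-squared against the fitted curve is reported as
#' an overdispersion diagnostic (vials are pooled per dose in the fit).
#' Complete separation (no partial-mortality dose) yields a flagged fit with
#' an unbounded confidence interval rather than an error.
#'
#' @param records data.frame of dose-response records with columns `dose`,
#'   `n_exposed`, `n_dead` (optionally `population`, `insecticide`).
#' @param control_correction Apply Abbott's correction using dose-0 records.
#' @param conf_level Confidence level for the LD50 interval.
#' @return A `ProbitFit`: list with `intercept`, `slope` (per log10 dose),
#'   `ld50`, `se_log10_ld50`, `ci` (dose scale), `loglik`, `converged`,
#'   `separated`, `heterogeneity` (statistic, df, p), `n_records`.
#' @export
fit_probit <- function(records, control_correction = FALSE,
                       conf_level = 0.95) {
  records <- as.data.frame(records)
  req <- c("dose", "n_exposed", "n_dead")
  if (!all(req %in% names(records))) {
    stopf("records need columns %s", paste(req, collapse = ", "))
  }
  if (any(records$n_dead > records$n_exposed) || any(records$n_dead < 0)) {
    stopf("need 0 <= n_dead <= n_exposed")
  }
  if (any(records$dose < 0)) stopf("doses must be non-negative")
  pos <- records[records$dose > 0, , drop = FALSE]
  if (length(unique(pos$dose)) < 3) {
    stopf("need at least 3 distinct positive doses to fit a probit curve")
  }
  dead <- pos$n_dead
  if (control_correction) {
    ctrl <- records[records$dose == 0, , drop = FALSE]
    cmort <- if (nrow(ctrl)) sum(ctrl$n_dead) / sum(ctrl$n_exposed) else 0
    if (cmort > 0) {
      prop <- clamp((dead / pos$n_exposed - cmort) / (1 - cmort), 0, 1)
      dead <- round(prop * pos$n_exposed)
    }
  }
  separated <- !any(dead > 0 & dead < pos$n_exposed)
  fit <- suppressWarnings(
    stats::glm(cbind(dead, pos$n_exposed - dead) ~ log10(pos$dose),
               family = stats::binomial(link = "probit")))
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  ld50 <- 10^(-a / b)
  v <- stats::vcov(fit)
  g <- c(-1 / b, a / b^2)
  se <- sqrt(drop(t(g) %*% v %*% g))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (separated || !is.finite(se) || se > 100) {
    ci <- c(0, Inf)
    se <- Inf
  } else {
    ci <- 10^(log10(ld50) + c(-1, 1) * zq * se)
  }
  if (is.finite(b) && b <= 0) {
    warnf("fitted probit slope is not positive; mortality decreases with dose")
  }
  mu <- stats::fitted(fit)
  pearson <- sum((dead - pos$n_exposed * mu)^2 /
                   pmax(pos$n_exposed * mu * (1 - mu), 1e-12))
  het_df <- nrow(pos) - 2L
  structure(list(intercept = a, slope = b, ld50 = ld50,
                 se_log10_ld50 = se, ci = ci,
                 loglik = probit_loglik(pos, a, b),
                 converged = isTRUE(fit$converged) && !separated,
                 separated = separated,
                 heterogeneity = list(statistic = pearson, df = het_df,
                                      p = stats::pchisq(pearson, pmax(het_df, 1),
                                                        lower.tail = FALSE)),
                 n_records = nrow(pos)),
            class = "ProbitFit")
}

#' @export
print.ProbitFit <- function(x, ...) {
  cat(sprintf("LD50 = %.4g [%.4g, %.4g] (probit slope %.3f per log10 dose)\n",
              x$ld50, x$ci[1], x$ci[2], x$slope))
  if (x$separated) cat("  flag: complete separation; CI unbounded\n")
  invisible(x)
}

#' Summarize single-dose bioassay mortality per population
#'
#' Per population (and insecticide), computes the mean of per-vial mortality
#' fractions and the standard error of the mean across vials. Vials with
#' zero exposed flies are dropped with a warning; the SEM of a single vial
#' is `NA`.
#'
#' @param records data.frame with columns `population`, `dose`, `n_exposed`,
#'   `n_dead` (optionally `insecticide`).
#' @return data.frame with columns `population`, `insecticide`, `n_vials`,
#'   `mean_mortality`, `sem`.
#' @export
single_dose_summary <- function(records) {
  records <- as.data.frame(records)
  if (is.null(records$insecticide)) records$insecticide <- "all"
  bad <- records$n_exposed == 0
  if (any(bad)) {
    warnf("dropping %d vial(s) with zero exposed flies", sum(bad))
    records <- records[!bad, , drop = FALSE]
  }
  if (!nrow(records)) stopf("no usable vials")
  key <- interaction(records$population, records$insecticide, drop = TRUE)
  out <- lapply(split(records, key), function(d) {
    m <- d$n_dead / d$n_exposed
    data.frame(population = d$population[1], insecticide = d$insecticide[1],
               n_vials = nrow(d), mean_mortality = mean(m),
               sem = if (nrow(d) > 1) stats::sd(m) / sqrt(nrow(d)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
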