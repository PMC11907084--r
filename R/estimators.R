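new_mr_estimate <- function(method, beta, se, n_snp, extra = list()) {
  stopifnot(se > 0)
  out <- c(list(method = method, beta = beta, se = se,
                ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                pval = two_sided_p(beta / se), n_snp = as.integer(n_snp)),
           extra)
  structure(out, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d SNPs): beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], OR = %.2f, p = %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$ci_low, x$ci_high,
              exp(x$beta), x$pval))
  invisible(x)
}

ratio_estimates <- function(h) {
  if (any(h$bx_1 == 0)) abort("undefined Wald ratio: a SNP has zero exposure effect")
  tibble::tibble(snp = h$snp,
                 ratio = h$by / h$bx_1,
                 ratio_se = h$sey / abs(h$bx_1),
                 w = h$bx_1^2 / h$sey^2)
}

#' Wald ratio for a single SNP
#'
#' The single-instrument causal estimate: `beta = by / bx`, with the
#' first-order standard error `sey / |bx|`.
#'
#' @param bx,sex SNP-exposure effect and SE.
#' @param by,sey SNP-outcome effect and SE.
#' @return An `mr_estimate` with method tag `WALD`.
#' @export
#' @examples
#' wald_ratio(0.1, 0.01, 0.05, 0.01)
wald_ratio <- function(bx, sex, by, sey) {
  if (bx == 0) abort("undefined Wald ratio: bx = 0")
  new_mr_estimate("WALD", beta = by / bx, se = sey / abs(bx), n_snp = 1)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' through the origin with weights `1/sey^2`:
#' `beta = sum(bx*by/sey^2) / sum(bx^2/sey^2)`. The fixed-effect SE is
#' `1/sqrt(sum(bx^2/sey^2))`; the random-effect (multiplicative
#' overdispersion) SE scales it by `max(1, sqrt(Q/df))`.
#'
#' @param h Harmonised set with one exposure.
#' @param mode `"fixed"` or `"random"`.
#' @return An `mr_estimate` (`IVW_FIXED` or `IVW_RANDOM`) carrying the
#'   heterogeneity diagnostics in `$heterogeneity`.
#' @export
mr_ivw <- function(h, mode = c("fixed", "random")) {
  mode <- match.arg(mode)
  n <- nrow(h)
  if (n < 1) abort("empty harmonised set")
  if (mode == "random" && n < 2) abort("random-effects IVW needs at least 2 SNPs")
  w <- 1 / h$sey^2
  sw <- sum(h$bx_1^2 * w)
  beta <- sum(h$bx_1 * h$by * w) / sw
  se <- 1 / sqrt(sw)
  het <- if (n >= 2) cochran_q(h, beta) else NULL
  if (mode == "random") se <- se * max(1, sqrt(het$Q / het$df))
  new_mr_estimate(if (mode == "fixed") "IVW_FIXED" else "IVW_RANDOM",
                  beta, se, n, extra = list(heterogeneity = het))
}

#' Cochran's Q heterogeneity test for per-SNP ratio estimates
#'
#' `Q = sum w_j (by_j/bx_j - beta)^2` with first-order weights
#' `w_j = bx_j^2 / sey_j^2`, df = n - 1, upper-tail chi-square p, and
#' `I^2 = max(0, (Q - df) / Q)`.
#'
#' @param h Harmonised set with one exposure (needs >= 2 SNPs).
#' @param beta The causal estimate the SNP ratios are compared against
#'   (typically the IVW estimate).
#' @return A list (`mr_heterogeneity`) with `Q`, `df`, `pval`, `i2`.
#' @export
cochran_q <- function(h, beta) {
  n <- nrow(h)
  if (n < 2) abort("Cochran's Q needs at least 2 SNPs")
  r <- ratio_estimates(h)
  Q <- sum(r$w * (r$ratio - beta)^2)
  df <- n - 1
  i2 <- if (Q > 0) max(0, (Q - df) / Q) else 0
  structure(list(Q = Q, df = df, pval = pchisq(Q, df, lower.tail = FALSE),
                 i2 = i2),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df (p = %.3g), I2 = %.1f%%\n",
              x$Q, x$df, x$pval, 100 * x$i2))
  invisible(x)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an intercept (weights `1/sey^2`), after orienting every SNP so its
#' exposure effect is non-negative. The slope is the pleiotropy-adjusted
#' causal estimate; the intercept and its two-sided p-value form the
#' directional-pleiotropy (Egger intercept) test.
#'
#' @param h Harmonised set with one exposure and >= 3 SNPs.
#' @return A list with `estimate` (an `mr_estimate`, method `EGGER`) and
#'   `pleiotropy` (list with `intercept`, `se`, `pval`).
#' @export
mr_egger <- function(h) {
  n <- nrow(h)
  if (n < 3) abort("MR-Egger needs at least 3 SNPs")
  flip <- sign(h$bx_1)
  flip[flip == 0] <- 1
  bx <- h$bx_1 * flip
  by <- h$by * flip
  w <- 1 / h$sey^2
  fit <- lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  # multiplicative random-effects scaling, floored at 1 (common Egger practice)
  scale <- max(1, sigma)
  slope_se <- cf["bx", "Std. Error"] / sigma * scale
  int_se <- cf["(Intercept)", "Std. Error"] / sigma * scale
  est <- new_mr_estimate("EGGER", cf["bx", "Estimate"], slope_se, n)
  pl <- structure(list(intercept = cf["(Intercept)", "Estimate"],
                       se = int_se,
                       pval = two_sided_p(cf["(Intercept)", "Estimate"] / int_se)),
                  class = "mr_pleiotropy")
  list(estimate = est, pleiotropy = pl)
}

#' @export
print.mr_pleiotropy <- function(x, ...) {
  cat(sprintf("Egger intercept = %.4f (SE %.4f), p = %.3g\n",
              x$intercept, x$se, x$pval))
  invisible(x)
}

weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  ratio <- ratio[o]; w <- w[o] / sum(w)
  s <- cumsum(w)
  p <- s - w / 2
  if (p[1] >= 0.5) return(ratio[1])
  if (p[length(p)] <= 0.5) return(ratio[length(p)])
  below <- max(which(p < 0.5))
  ratio[below] + (ratio[below + 1] - ratio[below]) *
    (0.5 - p[below]) / (p[below + 1] - p[below])
}

#' Weighted and penalised weighted median estimators
#'
#' Orders the per-SNP Wald ratios and takes the inverse-variance-weighted
#' 50th percentile (midpoint rule with linear interpolation), which is
#' consistent when at least half the weight comes from valid instruments.
#' The penalised variant first multiplies each weight by
#' `min(1, 20 * q_j)`, where `q_j` is the chi-square(1) upper-tail p of SNP
#' j's heterogeneity contribution at the unpenalised estimate. The SE is a
#' parametric bootstrap over the summary statistics.
#'
#' @param h Harmonised set with one exposure and >= 3 SNPs.
#' @param penalized Use penalised weights?
#' @param n_boot Bootstrap replicates for the SE (default 500).
#' @param seed Optional integer seed for the bootstrap.
#' @return An `mr_estimate` (method `WMEDIAN` or `PWMEDIAN`).
#' @export
mr_weighted_median <- function(h, penalized = FALSE, n_boot = 500, seed = NULL) {
  n <- nrow(h)
  if (n < 3) abort("weighted median needs at least 3 SNPs")
  r <- ratio_estimates(h)
  weight_fun <- function(ratio, w) {
    if (!penalized) return(w)
    est0 <- weighted_median_point(ratio, w)
    qj <- pchisq(w * (ratio - est0)^2, df = 1, lower.tail = FALSE)
    w * pmin(1, 20 * qj)
  }
  beta <- weighted_median_point(r$ratio, weight_fun(r$ratio, r$w))
  if (!is.null(seed)) set.seed(seed)
  boot <- replicate(n_boot, {
    bx <- rnorm(n, h$bx_1, h$sex_1)
    by <- rnorm(n, h$by, h$sey)
    ratio <- by / bx
    w <- bx^2 / h$sey^2
    weighted_median_point(ratio, weight_fun(ratio, w))
  })
  new_mr_estimate(if (penalized) "PWMEDIAN" else "WMEDIAN",
                  beta, sd(boot), n)
}

# Profile -log-likelihood: per-SNP means xi_j maximised out analytically,
# leaving the quadratic form in theta (normalising constants dropped).
ml_profile_negloglik <- function(theta, h) {
  sum((h$by - theta * h$bx_1)^2 / (h$sey^2 + theta^2 * h$sex_1^2)) / 2
}

#' Maximum-likelihood causal estimate
#'
#' Models each SNP's observed effects as independent normals with means
#' `(xi_j, theta * xi_j)` and SDs `(sex_j, sey_j)`; the per-SNP means are
#' profiled out analytically and `theta` maximised numerically. The SE
#' comes from the observed (profile) information.
#'
#' @param h Harmonised set with one exposure.
#' @param tol Convergence tolerance for the 1-d optimiser.
#' @return An `mr_estimate` with method tag `ML`.
#' @export
mr_max_likelihood <- function(h, tol = 1e-10) {
  n <- nrow(h)
  if (n < 1) abort("empty harmonised set")
  start <- mr_ivw(h, "fixed")$beta
  width <- max(1, 10 * abs(start))
  opt <- optimize(ml_profile_negloglik, interval = c(start - width, start + width),
                  h = h, tol = tol)
  theta <- opt$minimum
  if (min(abs(theta - (start + c(-width, width)))) < 1e-6 * width) {
    abort(paste0("maximum-likelihood estimate did not converge inside the search ",
                 "interval (tol = ", tol, ", interval half-width = ", width, ")"))
  }
  eps <- 1e-4 * max(1, abs(theta))
  info <- (ml_profile_negloglik(theta + eps, h) - 2 * opt$objective +
             ml_profile_negloglik(theta - eps, h)) / eps^2
  if (!is.finite(info) || info <= 0) abort("non-positive observed information")
  new_mr_estimate("ML", theta, 1 / sqrt(info), n)
}

#' Radial IVW with modified second-order weights
#'
#' Regresses `sqrt(w_j) * (by_j / bx_j)` on `sqrt(w_j)` without intercept,
#' where `w_j = 1 / (sey_j^2/bx_j^2 + by_j^2 * sex_j^2 / bx_j^4)` are the
#' modified second-order weights that acknowledge uncertainty in the
#' SNP-exposure effects.
#'
#' @param h Harmonised set with one exposure.
#' @return An `mr_estimate` with method tag `RADIAL_IVW`.
#' @export
mr_radial_ivw <- function(h) {
  if (any(h$bx_1 == 0)) abort("radial IVW undefined: a SNP has zero exposure effect")
  n <- nrow(h)
  w <- 1 / (h$sey^2 / h$bx_1^2 + h$by^2 * h$sex_1^2 / h$bx_1^4)
  ratio <- h$by / h$bx_1
  beta <- sum(w * ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  new_mr_estimate("RADIAL_IVW", beta, se, n)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect with each SNP omitted in turn and reports
#' the maximum absolute deviation from the full-sample estimate.
#'
#' @param h Harmonised set with one exposure and >= 3 SNPs.
#' @param method Estimator to use: `"ivw_fixed"` (default), `"ivw_random"`,
#'   `"egger"`, `"wmedian"`, or `"ml"`.
#' @return A list with `full` (the full-set `mr_estimate`), `loo` (tibble of
#'   per-omission estimates) and `max_abs_deviation`.
#' @export
mr_leave_one_out <- function(h, method = c("ivw_fixed", "ivw_random", "egger",
                                           "wmedian", "ml")) {
  method <- match.arg(method)
  n <- nrow(h)
  if (n < 3) abort("leave-one-out needs at least 3 SNPs")
  fit <- function(hh) {
    switch(method,
           ivw_fixed = mr_ivw(hh, "fixed"),
           ivw_random = mr_ivw(hh, "random"),
           egger = mr_egger(hh)$estimate,
           wmedian = mr_weighted_median(hh, seed = 1),
           ml = mr_max_likelihood(hh))
  }
  full <- fit(h)
  loo <- purrr::map_dfr(seq_len(n), function(i) {
    e <- fit(h[-i, ])
    tibble::tibble(omitted = h$snp[i], beta = e$beta, se = e$se,
                   ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval)
  })
  list(full = full, loo = loo,
       max_abs_deviation = max(abs(loo$beta - full$beta)))
}

#' Statistical power for two-sample MR with a binary outcome
#'
#' Normal-approximation power of a level-`alpha` two-sided z-test, with
#' non-centrality `sqrt(n * r2_gx * cf * (1 - cf)) * |log(or_alt)|` where
#' `cf` is the case fraction of the outcome study and `r2_gx` the exposure
#' variance explained by the instruments.
#'
#' @param n Outcome-study sample size.
#' @param case_fraction Proportion of cases, in (0, 1).
#' @param r2_gx Instrument r-squared for the exposure, in (0, 1).
#' @param or_alt Odds ratio under the alternative.
#' @param alpha Significance level (default 0.05).
#' @return Power in [0, 1].
#' @export
#' @examples
#' power_binary(2e5, 0.3, 0.02, 1.2)
power_binary <- function(n, case_fraction, r2_gx, or_alt, alpha = 0.05) {
  stopifnot(n > 0, case_fraction > 0, case_fraction < 1,
            r2_gx > 0, r2_gx < 1, or_alt > 0, alpha > 0, alpha < 1)
  ncp <- sqrt(n * r2_gx * case_fraction * (1 - case_fraction)) * abs(log(or_alt))
  zc <- qnorm(1 - alpha / 2)
  pnorm(-zc + ncp) + pnorm(-zc - ncp)
}
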