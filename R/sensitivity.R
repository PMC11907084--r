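#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' The global test compares the observed leave-one-out weighted residual sum
#' of squares to its parametric null distribution (`n_sim` simulations of
#' the summary statistics under the leave-one-out fits). The per-SNP outlier
#' test compares each SNP's observed residual to its simulated distribution
#' with a Bonferroni-adjusted threshold (`outlier_alpha / n_snp`), applied
#' when the global test is significant. If outliers are flagged, the
#' distortion test compares the change in the IVW estimate after removing
#' them to the change after removing random SNP subsets of the same size,
#' and a corrected IVW estimate on the retained SNPs is returned.
#'
#' @param h Harmonised set with one exposure and >= 4 SNPs.
#' @param n_sim Number of parametric simulations (default 1000).
#' @param outlier_alpha Family-wise level of the outlier test (default 0.05).
#' @param seed Integer seed; the whole procedure is seed-reproducible.
#' @return A list with `global_p`, `outliers` (character vector of SNP ids),
#'   `outlier_pvals` (per-SNP empirical p), `distortion_p` (NA when no
#'   outlier), and `corrected` (IVW `mr_estimate` on the retained SNPs).
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  n <- nrow(h)
  if (n < 4) abort("MR-PRESSO needs at least 4 SNPs")
  set.seed(seed)
  w <- 1 / h$sey^2

  loo_betas <- function(bx, by) {
    num <- bx * by * w; den <- bx^2 * w
    (sum(num) - num) / (sum(den) - den)
  }
  rss_of <- function(bx, by) {
    b <- loo_betas(bx, by)
    w * (by - b * bx)^2
  }

  obs_res <- rss_of(h$bx_1, h$by)
  obs_rss <- sum(obs_res)

  b_loo <- loo_betas(h$bx_1, h$by)
  sim_rss <- numeric(n_sim)
  exceed <- numeric(n)
  for (s in seq_len(n_sim)) {
    bx_s <- rnorm(n, h$bx_1, h$sex_1)
    by_s <- rnorm(n, b_loo * h$bx_1, h$sey)
    res_s <- rss_of(bx_s, by_s)
    sim_rss[s] <- sum(res_s)
    exceed <- exceed + (res_s >= obs_res)
  }
  global_p <- (1 + sum(sim_rss >= obs_rss)) / (n_sim + 1)
  outlier_p <- exceed / n_sim

  outliers <- character(0)
  if (global_p < outlier_alpha) {
    outliers <- h$snp[outlier_p < outlier_alpha / n]
  }

  ivw_beta <- function(idx) {
    sum(h$bx_1[idx] * h$by[idx] * w[idx]) / sum(h$bx_1[idx]^2 * w[idx])
  }
  distortion_p <- NA_real_
  retained_idx <- seq_len(n)
  if (length(outliers) > 0 && length(outliers) < n - 1) {
    retained_idx <- which(!h$snp %in% outliers)
    beta_all <- ivw_beta(seq_len(n))
    beta_clean <- ivw_beta(retained_idx)
    d_obs <- 100 * (beta_clean - beta_all) / abs(beta_clean)
    d_null <- replicate(n_sim, {
      rm_idx <- sample(retained_idx, length(outliers))
      b <- ivw_beta(setdiff(seq_len(n), rm_idx))
      100 * (b - beta_all) / abs(b)
    })
    distortion_p <- mean(abs(d_null) >= abs(d_obs))
  }
  corrected <- mr_ivw(h[retained_idx, ], "fixed")
  list(global_p = global_p, outliers = outliers, outlier_pvals =
         setNames(outlier_p, h$snp), distortion_p = distortion_p,
       corrected = corrected)
}

#' SIMEX-corrected IVW estimate
#'
#' Simulation-extrapolation correction for measurement error in the
#' SNP-exposure effects (the NOME violation): for each lambda in the grid,
#' extra noise `sqrt(lambda) * sex_j` is added to the exposure effects
#' `n_boot` times and the IVW estimate averaged; a quadratic in lambda is
#' then extrapolated back to lambda = -1 (the error-free limit). The SE is
#' a nonparametric bootstrap over SNPs of the whole procedure.
#'
#' @param h Harmonised set with one exposure and >= 3 SNPs.
#' @param lambdas Noise-inflation grid; must contain 0 (default
#'   `c(0, 0.5, 1, 1.5, 2)`). A grid of `{0}` alone returns the plain IVW
#'   estimate.
#' @param n_boot Inner simulation replicates per lambda (default 200).
#' @param n_boot_se Outer bootstrap replicates for the SE (default 100).
#' @param seed Integer seed.
#' @return An `mr_estimate` with method tag `IVW_SIMEX`.
#' @export
mr_simex_ivw <- function(h, lambdas = c(0, 0.5, 1, 1.5, 2), n_boot = 200,
                         n_boot_se = 100, seed = 1) {
  if (!any(lambdas == 0)) abort("SIMEX lambda grid must include 0")
  n <- nrow(h)
  if (length(lambdas) == 1) {
    return(mr_ivw(h, "fixed"))
  }
  if (n < 3) abort("SIMEX needs at least 3 SNPs")
  set.seed(seed)

  ivw_beta <- function(bx, by, sey) {
    w <- 1 / sey^2
    sum(bx * by * w) / sum(bx^2 * w)
  }
  simex_point <- function(bx, sex, by, sey, inner) {
    mean_beta <- vapply(lambdas, function(l) {
      if (l == 0) return(ivw_beta(bx, by, sey))
      mean(replicate(inner, ivw_beta(bx + sqrt(l) * sex * rnorm(length(bx)),
                                     by, sey)))
    }, numeric(1))
    fit <- lm(mean_beta ~ lambdas + I(lambdas^2))
    unname(coef(fit)[1] - coef(fit)[2] + coef(fit)[3])
  }

  beta <- simex_point(h$bx_1, h$sex_1, h$by, h$sey, n_boot)
  boots <- replicate(n_boot_se, {
    idx <- sample.int(n, n, replace = TRUE)
    simex_point(h$bx_1[idx], h$sex_1[idx], h$by[idx], h$sey[idx],
                inner = max(25, n_boot %/% 4))
  })
  new_mr_estimate("IVW_SIMEX", beta, sd(boots), n)
}
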