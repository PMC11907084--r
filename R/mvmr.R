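new_mvmr_estimate <- function(method, exposure_names, betas, ses, extra = list()) {
  stopifnot(all(ses > 0, na.rm = TRUE))
  out <- c(list(method = method,
                exposure_names = exposure_names,
                betas = setNames(betas, exposure_names),
                ses = setNames(ses, exposure_names),
                ci_low = setNames(betas - Z95 * ses, exposure_names),
                ci_high = setNames(betas + Z95 * ses, exposure_names),
                pvals = setNames(two_sided_p(betas / ses), exposure_names)),
           extra)
  structure(out, class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d SNPs):\n", x$method, x$n_snp))
  for (nm in x$exposure_names) {
    cat(sprintf("  %s: beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
                nm, x$betas[nm], x$ses[nm], x$ci_low[nm], x$ci_high[nm],
                x$pvals[nm]))
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4f, p = %.3g\n", x$intercept, x$intercept_p))
  }
  invisible(x)
}

# Weighted regression of by on the exposure-effect columns. Columns that are
# identically zero are dropped from the fit and reported with beta = 0 and
# se = NA (the degenerate single-exposure reduction); genuine collinearity
# among non-zero columns is an error.
mvmr_wls <- function(X, by, w, exposure_names, intercept = FALSE) {
  nonzero <- colSums(X != 0) > 0
  Xf <- X[, nonzero, drop = FALSE]
  if (ncol(Xf) == 0) abort("all exposure-effect columns are zero")
  if (qr(sqrt(w) * cbind(if (intercept) 1, Xf))$rank < ncol(Xf) + intercept) {
    abort(paste0("rank-deficient multivariable design; collinear exposures: ",
                 paste(exposure_names[nonzero], collapse = ", ")))
  }
  fit <- if (intercept) lm(by ~ Xf, weights = w) else lm(by ~ Xf - 1, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  scale <- max(1, sigma)                    # multiplicative overdispersion, floored
  cf <- sm$coefficients
  slope_rows <- grep("^Xf", rownames(cf))
  betas <- rep(0, length(exposure_names))
  ses <- rep(NA_real_, length(exposure_names))
  betas[nonzero] <- cf[slope_rows, "Estimate"]
  ses[nonzero] <- cf[slope_rows, "Std. Error"] / sigma * scale
  q <- sum(w * fit$residuals^2)
  out <- list(betas = betas, ses = ses, q = q,
              df = length(by) - ncol(Xf) - intercept)
  if (intercept) {
    out$intercept <- cf["(Intercept)", "Estimate"]
    out$intercept_se <- cf["(Intercept)", "Std. Error"] / sigma * scale
  }
  out
}

#' Multivariable IVW estimator
#'
#' Weighted least squares of the outcome effects on all exposures'
#' SNP-effect columns without intercept, weights `1/sey^2`. SEs use the
#' weighted-regression covariance with multiplicative overdispersion
#' floored at 1. The mediator-adjusted effect in two-step mediation is the
#' mediator's coefficient from this fit.
#'
#' @param h Harmonised set with K >= 1 exposures and more SNPs than
#'   exposures.
#' @return An `mvmr_estimate` with method tag `MV_IVW`, including the
#'   heterogeneity statistic `q` and conditional F-statistics `cond_f`.
#' @export
mvmr_ivw <- function(h) {
  k <- n_exposures(h)
  n <- nrow(h)
  if (n <= k) abort("multivariable IVW needs more SNPs than exposures")
  X <- harm_bx(h, "beta")
  w <- 1 / h$sey^2
  fit <- mvmr_wls(X, h$by, w, attr(h, "exposure_names"))
  new_mvmr_estimate("MV_IVW", attr(h, "exposure_names"), fit$betas, fit$ses,
                    extra = list(n_snp = n, q = fit$q, q_df = fit$df,
                                 q_pval = pchisq(fit$q, fit$df, lower.tail = FALSE),
                                 i2 = if (fit$q > 0) max(0, (fit$q - fit$df) / fit$q) else 0,
                                 cond_f = conditional_f(h)))
}

# Conditional instrument strength: regress each exposure's SNP effects on
# the others' and compute the mean F of the residual signal. Reported as a
# diagnostic only; no hard filter is applied.
conditional_f <- function(h) {
  k <- n_exposures(h)
  X <- harm_bx(h, "beta")
  S <- harm_bx(h, "se")
  vapply(seq_len(k), function(i) {
    res <- if (k == 1) X[, 1] else lm(X[, i] ~ X[, -i, drop = FALSE] - 1)$residuals
    mean(res^2 / S[, i]^2)
  }, numeric(1)) |> setNames(attr(h, "exposure_names"))
}

#' Multivariable MR-Egger estimator
#'
#' As [mvmr_ivw()] plus an intercept, after flipping each SNP's signs so
#' that the orienting exposure's effect is non-negative. The intercept and
#' its p-value form the multivariable pleiotropy test.
#'
#' @param h Harmonised set with K >= 1 exposures.
#' @param orient_to Index of the exposure used to orient SNP signs
#'   (default 1).
#' @return An `mvmr_estimate` with method tag `MV_EGGER` and fields
#'   `intercept`, `intercept_se`, `intercept_p`.
#' @export
mvmr_egger <- function(h, orient_to = 1) {
  k <- n_exposures(h)
  n <- nrow(h)
  if (n <= k + 1) abort("multivariable Egger needs more SNPs than exposures + 1")
  X <- harm_bx(h, "beta")
  flip <- sign(X[, orient_to])
  flip[flip == 0] <- 1
  X <- X * flip
  by <- h$by * flip
  w <- 1 / h$sey^2
  fit <- mvmr_wls(X, by, w, attr(h, "exposure_names"), intercept = TRUE)
  new_mvmr_estimate("MV_EGGER", attr(h, "exposure_names"), fit$betas, fit$ses,
                    extra = list(n_snp = n, q = fit$q, q_df = fit$df,
                                 q_pval = pchisq(fit$q, fit$df, lower.tail = FALSE),
                                 i2 = if (fit$q > 0) max(0, (fit$q - fit$df) / fit$q) else 0,
                                 intercept = fit$intercept,
                                 intercept_se = fit$intercept_se,
                                 intercept_p = two_sided_p(fit$intercept / fit$intercept_se)))
}

qhet_objective <- function(theta, X, S, by, sey) {
  denom <- sey^2 + as.vector(S^2 %*% theta^2)
  sum((by - as.vector(X %*% theta))^2 / denom)
}

#' Q-minimising multivariable estimator (QHET)
#'
#' Estimates the causal effects by minimising the heterogeneity statistic
#' `Q(theta) = sum_j (by_j - sum_k theta_k bx_jk)^2 /
#' (sey_j^2 + sum_k theta_k^2 sex_jk^2)`, whose denominator propagates the
#' uncertainty of the exposure effects (weak-instrument-robust weights).
#' Optimisation starts from the multivariable IVW estimate; confidence
#' intervals come from a nonparametric bootstrap over SNPs.
#'
#' @param h Harmonised set with K >= 1 exposures.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An `mvmr_estimate` with method tag `QHET`; `q` holds the
#'   minimised statistic and `ci_low`/`ci_high` the bootstrap percentile
#'   bounds (SEs are bootstrap SDs).
#' @export
mvmr_qhet <- function(h, n_boot = 1000, seed = 1) {
  k <- n_exposures(h)
  n <- nrow(h)
  if (n <= k) abort("QHET needs more SNPs than exposures")
  X <- harm_bx(h, "beta")
  S <- harm_bx(h, "se")
  start <- mvmr_ivw(h)$betas
  start[is.na(start)] <- 0

  minimise <- function(X, S, by, sey, start) {
    opt <- optim(start, qhet_objective, X = X, S = S, by = by, sey = sey,
                 method = if (length(start) == 1) "Brent" else "Nelder-Mead",
                 lower = if (length(start) == 1) start - 10 - abs(start) else -Inf,
                 upper = if (length(start) == 1) start + 10 + abs(start) else Inf,
                 control = list(maxit = 2000, reltol = 1e-12))
    if (opt$convergence != 0) {
      abort(paste0("QHET optimiser failed to converge (code ", opt$convergence,
                   "): ", opt$message %||% ""))
    }
    opt
  }
  opt <- minimise(X, S, h$by, h$sey, start)

  set.seed(seed)
  boot <- replicate(n_boot, {
    idx <- sample.int(n, n, replace = TRUE)
    minimise(X[idx, , drop = FALSE], S[idx, , drop = FALSE],
             h$by[idx], h$sey[idx], opt$par)$par
  })
  boot <- matrix(boot, nrow = k)
  ses <- pmax(apply(boot, 1, sd), .Machine$double.eps)  # exact fits give sd 0
  ci <- apply(boot, 1, quantile, probs = c(0.025, 0.975))
  est <- new_mvmr_estimate("QHET", attr(h, "exposure_names"), opt$par, ses,
                           extra = list(n_snp = n, q = opt$value,
                                        q_df = n - k,
                                        q_pval = pchisq(opt$value, n - k,
                                                        lower.tail = FALSE),
                                        i2 = if (opt$value > 0)
                                          max(0, (opt$value - (n - k)) / opt$value) else 0))
  est$ci_low <- setNames(ci[1, ], attr(h, "exposure_names"))
  est$ci_high <- setNames(ci[2, ], attr(h, "exposure_names"))
  est
}
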