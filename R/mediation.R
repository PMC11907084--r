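#' Total effect of the exposure on the outcome (beta_c)
#'
#' Runs instrument selection, exclusion filtering and harmonisation, then
#' the univariable estimator chosen by the pleiotropy/heterogeneity
#' decision tree.
#'
#' @param exposure,outcome Summary-statistics tibbles.
#' @param settings An [mr_settings()] list.
#' @param blacklist,ld Passed to the selection/exclusion steps.
#' @return An `mr_estimate` with the method choice in `$choice` and
#'   diagnostics in `$analysis`.
#' @export
total_effect <- function(exposure, outcome, settings = mr_settings(),
                         blacklist = character(), ld = NULL) {
  res <- univariable_analysis(exposure, outcome, settings, blacklist, ld)
  est <- res$estimate
  est$choice <- res$choice
  est$analysis <- res
  est
}

#' Exposure-to-mediator effect (beta_a)
#'
#' The first step of two-step mediation: a univariable MR of the mediator
#' on the exposure, identical to [total_effect()] with the mediator in the
#' outcome role.
#'
#' @inheritParams total_effect
#' @param mediator Mediator summary-statistics tibble.
#' @return An `mr_estimate`.
#' @export
step1_effect <- function(exposure, mediator, settings = mr_settings(),
                         blacklist = character(), ld = NULL) {
  total_effect(exposure, mediator, settings, blacklist, ld)
}

#' Mediator-to-outcome effect adjusted for the exposure (beta_b)
#'
#' The second step of two-step mediation: instruments for the exposure and
#' the mediator are combined, harmonised across all three studies
#' ([harmonize_multi()]), and the multivariable estimator chosen by the
#' multivariable decision tree is fitted. The mediator's coefficient is
#' beta_b; the exposure's coefficient estimates the direct effect.
#'
#' @inheritParams step1_effect
#' @param outcome Outcome summary-statistics tibble.
#' @return An `mvmr_estimate` with the method choice in `$choice`.
#' @export
step2_effect <- function(exposure, mediator, outcome,
                         settings = mr_settings(), blacklist = character(),
                         ld = NULL) {
  iv_exp <- select_instruments(exposure, p_threshold = settings$p_threshold,
                               ld = ld, r2_max = settings$r2_max,
                               window_bp = settings$window_bp)
  iv_exp <- apply_exclusions(iv_exp, blacklist = blacklist,
                             outcome_ids = outcome$snp,
                             eaf_ambiguity_band = settings$eaf_band)
  iv_med <- select_instruments(mediator, p_threshold = settings$p_threshold,
                               ld = ld, r2_max = settings$r2_max,
                               window_bp = settings$window_bp)
  iv_med <- apply_exclusions(iv_med, blacklist = blacklist,
                             outcome_ids = outcome$snp,
                             eaf_ambiguity_band = settings$eaf_band)
  h <- harmonize_multi(exposure, mediator, outcome, iv_exp, iv_med,
                       ld = ld, r2_max = settings$r2_max,
                       eaf_ambiguity_band = settings$eaf_band,
                       exposure_names = c("exposure", "mediator"))
  mv_ivw <- mvmr_ivw(h)
  eg <- mvmr_egger(h)
  het <- list(Q = mv_ivw$q, pval = mv_ivw$q_pval, i2 = mv_ivw$i2)
  choice <- select_mvmr_method(eg$intercept_p, het)
  est <- switch(choice$chosen,
                MV_EGGER = eg,
                QHET = mvmr_qhet(h, n_boot = 200),
                MV_IVW = mv_ivw)
  est$choice <- choice
  est$harmonized <- h
  est
}

#' Indirect (mediation) effect with delta-method inference
#'
#' The product-of-coefficients mediation effect `beta_a * beta_b`, its
#' delta-method standard error
#' `sqrt(beta_b^2 se_a^2 + beta_a^2 se_b^2)`, the Wald 95% CI, and the
#' Sobel test p-value (two-sided normal).
#'
#' @param beta_a,se_a Exposure-to-mediator effect and SE.
#' @param beta_b,se_b Adjusted mediator-to-outcome effect and SE.
#' @return A list with `mediation`, `se`, `ci_low`, `ci_high`, `sobel_p`.
#' @export
#' @examples
#' mediation_effect(0.73, (0.88 - 0.58) / 3.92, 0.05, (0.08 - 0.01) / 3.92)
mediation_effect <- function(beta_a, se_a, beta_b, se_b) {
  stopifnot(se_a > 0, se_b > 0)
  med <- beta_a * beta_b
  se <- sqrt(beta_b^2 * se_a^2 + beta_a^2 * se_b^2)
  sobel_p <- if (se > 0) two_sided_p(med / se) else 1
  if (med == 0) sobel_p <- 1
  list(mediation = med, se = se,
       ci_low = med - Z95 * se, ci_high = med + Z95 * se,
       sobel_p = sobel_p)
}

#' Proportion of the total effect mediated
#'
#' `100 * mediation / beta_c` (percent), with a delta-method CI for the
#' ratio assuming independence of the mediation and total-effect estimates:
#' `se = |proportion| * sqrt(mediation_se^2/mediation^2 + se_c^2/beta_c^2)`.
#' Proportions outside [0, 100] are allowed but flagged.
#'
#' @param mediation,mediation_se Indirect effect and its SE.
#' @param beta_c,se_c Total effect and its SE.
#' @return A list with `proportion` (percent), `se`, `ci_low`, `ci_high`,
#'   `flag` (`"ok"` or `"outside_0_100"`), and `ci_method` (`"delta-ratio"`).
#' @export
proportion_mediated <- function(mediation, mediation_se, beta_c, se_c) {
  if (beta_c == 0) abort("proportion mediated undefined: total effect is zero")
  stopifnot(mediation_se >= 0, se_c > 0)
  prop <- 100 * mediation / beta_c
  se <- if (mediation == 0) 100 * mediation_se / abs(beta_c) else
    abs(prop) * sqrt(mediation_se^2 / mediation^2 + se_c^2 / beta_c^2)
  list(proportion = prop, se = se,
       ci_low = prop - Z95 * se, ci_high = prop + Z95 * se,
       flag = if (prop < 0 || prop > 100) "outside_0_100" else "ok",
       ci_method = "delta-ratio")
}

#' Two-step MR mediation analysis
#'
#' Composes the full mediation workflow: total effect beta_c
#' (exposure -> outcome), step-1 effect beta_a (exposure -> mediator),
#' step-2 adjusted effect beta_b (mediator -> outcome given exposure,
#' multivariable MR), the indirect effect beta_a * beta_b with delta-method
#' CI and Sobel test, and the proportion mediated with its delta-ratio CI.
#'
#' @param exposure,mediator,outcome Summary-statistics tibbles.
#' @param settings An [mr_settings()] list.
#' @param blacklist,ld Passed through to every step.
#' @param exposure_name,outcome_name Labels used in the tidy output.
#' @return An object of class `mr_mediation` with fields `beta_c`, `se_c`,
#'   `beta_a`, `se_a`, `beta_b`, `se_b`, `mediation`, `mediation_se`,
#'   `mediation_ci`, `sobel_p`, `proportion`, `proportion_ci`, per-step
#'   method tags, and the per-step fitted objects in `$steps`.
#' @export
run_mediation <- function(exposure, mediator, outcome,
                          settings = mr_settings(), blacklist = character(),
                          ld = NULL, exposure_name = "exposure",
                          outcome_name = "outcome") {
  step_try <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("mediation step '", label, "' failed: ", conditionMessage(e)))
    })
  }
  tot <- step_try("total effect (beta_c)",
                  total_effect(exposure, outcome, settings, blacklist, ld))
  s1 <- step_try("step 1 (beta_a)",
                 step1_effect(exposure, mediator, settings, blacklist, ld))
  s2 <- step_try("step 2 (beta_b)",
                 step2_effect(exposure, mediator, outcome, settings, blacklist, ld))
  beta_b <- unname(s2$betas["mediator"])
  se_b <- unname(s2$ses["mediator"])
  med <- mediation_effect(s1$beta, s1$se, beta_b, se_b)
  prop <- proportion_mediated(med$mediation, med$se, tot$beta, tot$se)
  structure(
    list(exposure = exposure_name, outcome = outcome_name,
         beta_c = tot$beta, se_c = tot$se,
         beta_a = s1$beta, se_a = s1$se,
         beta_b = beta_b, se_b = se_b,
         mediation = med$mediation, mediation_se = med$se,
         mediation_ci = c(med$ci_low, med$ci_high),
         sobel_p = med$sobel_p,
         proportion = prop$proportion, proportion_se = prop$se,
         proportion_ci = c(prop$ci_low, prop$ci_high),
         proportion_flag = prop$flag,
         total_method = tot$method, step1_method = s1$method,
         step2_method = s2$method,
         steps = list(total = tot, step1 = s1, step2 = s2)),
    class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  ci <- function(b, s) sprintf("%.3f (%.3f, %.3f)", b, b - Z95 * s, b + Z95 * s)
  cat(sprintf("Two-step MR mediation: %s -> %s\n", x$exposure, x$outcome))
  cat("  total effect beta_c:  ", ci(x$beta_c, x$se_c), " [", x$total_method, "]\n", sep = "")
  cat("  step 1 beta_a:        ", ci(x$beta_a, x$se_a), " [", x$step1_method, "]\n", sep = "")
  cat("  step 2 beta_b:        ", ci(x$beta_b, x$se_b), " [", x$step2_method, "]\n", sep = "")
  cat(sprintf("  mediation effect:     %.3f (%.3f, %.3f), Sobel p = %.3g\n",
              x$mediation, x$mediation_ci[1], x$mediation_ci[2], x$sobel_p))
  cat(sprintf("  proportion mediated:  %.2f%% (%.2f%%, %.2f%%)%s\n",
              x$proportion, x$proportion_ci[1], x$proportion_ci[2],
              if (x$proportion_flag != "ok") " [outside 0-100%]" else ""))
  invisible(x)
}
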