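#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a univariable MR estimate into a one-row tibble
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A tibble with columns `method`, `n_snp`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `or`, `or_low`, `or_high`, `pval`.
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 or = exp(x$beta), or_low = exp(x$ci_low),
                 or_high = exp(x$ci_high), pval = x$pval)
}

#' Glance at a univariable MR estimate
#'
#' One-row model-level summary: heterogeneity diagnostics when available.
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mr_estimate <- function(x, ...) {
  het <- x$heterogeneity
  tibble::tibble(method = x$method, n_snp = x$n_snp,
                 q = het$Q %||% NA_real_, q_df = het$df %||% NA_integer_,
                 q_pval = het$pval %||% NA_real_, i2 = het$i2 %||% NA_real_)
}

#' Tidy a multivariable MR estimate (one row per exposure)
#'
#' @param x An `mvmr_estimate`.
#' @param ... Unused.
#' @return A tibble with one row per exposure.
#' @export
tidy.mvmr_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, exposure = x$exposure_names,
                 n_snp = x$n_snp, beta = unname(x$betas), se = unname(x$ses),
                 ci_low = unname(x$ci_low), ci_high = unname(x$ci_high),
                 or = exp(unname(x$betas)), or_low = exp(unname(x$ci_low)),
                 or_high = exp(unname(x$ci_high)), pval = unname(x$pvals))
}

#' Glance at a multivariable MR estimate
#'
#' @param x An `mvmr_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the heterogeneity statistic and, for
#'   Egger, the intercept test.
#' @export
glance.mvmr_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, n_snp = x$n_snp, q = x$q,
                 q_pval = x$q_pval %||% NA_real_, i2 = x$i2 %||% NA_real_,
                 intercept = x$intercept %||% NA_real_,
                 intercept_p = x$intercept_p %||% NA_real_)
}

#' Tidy a mediation result into a Table-style row
#'
#' Mirrors the reporting layout of two-step MR mediation tables: total
#' effect, step effects, mediation effect with CI, Sobel p and proportion
#' mediated with CI.
#'
#' @param x An `mr_mediation` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.mr_mediation <- function(x, ...) {
  tibble::tibble(
    exposure = x$exposure, outcome = x$outcome,
    beta_c = x$beta_c, beta_c_low = x$beta_c - Z95 * x$se_c,
    beta_c_high = x$beta_c + Z95 * x$se_c,
    beta_a = x$beta_a, beta_a_low = x$beta_a - Z95 * x$se_a,
    beta_a_high = x$beta_a + Z95 * x$se_a,
    beta_b = x$beta_b, beta_b_low = x$beta_b - Z95 * x$se_b,
    beta_b_high = x$beta_b + Z95 * x$se_b,
    mediation = x$mediation, mediation_low = x$mediation_ci[1],
    mediation_high = x$mediation_ci[2],
    sobel_p = x$sobel_p,
    proportion = x$proportion, proportion_low = x$proportion_ci[1],
    proportion_high = x$proportion_ci[2],
    proportion_flag = x$proportion_flag,
    total_method = x$total_method, step1_method = x$step1_method,
    step2_method = x$step2_method)
}

#' Glance at a mediation result
#' @param x An `mr_mediation` object.
#' @param ... Unused.
#' @return A one-row tibble of the headline quantities.
#' @export
glance.mr_mediation <- function(x, ...) {
  tibble::tibble(mediation = x$mediation, sobel_p = x$sobel_p,
                 proportion = x$proportion)
}

#' Serialise an estimate in the standard TSV dialect
#'
#' One row per estimate (per exposure for multivariable fits) with OR
#' columns, matching the package's report tables.
#'
#' @param x An `mr_estimate` or `mvmr_estimate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_estimate <- function(x, path) {
  readr::write_tsv(tidy(x), path, progress = FALSE)
  invisible(path)
}
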