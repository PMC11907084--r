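#' Choose the univariable estimator from pleiotropy and heterogeneity
#'
#' The primary-method decision tree: if the Egger intercept test is
#' significant (p < 0.05) use MR-Egger; otherwise, if there is significant
#' heterogeneity (I^2 > 25% and Cochran's Q p < 0.05) use random-effects
#' IVW; otherwise fixed-effect IVW.
#'
#' @param pleiotropy Egger intercept test result (list with `pval`).
#' @param het Heterogeneity result (list with `Q`, `df`, `pval`, `i2`).
#' @return A list (`mr_method_choice`) with `chosen`, the diagnostics, and
#'   `rationale` — the ordered trace of comparisons made.
#' @export
select_univariable_method <- function(pleiotropy, het) {
  rationale <- character(0)
  if (pleiotropy$pval < 0.05) {
    rationale <- sprintf("Egger intercept p = %.3g < 0.05: horizontal pleiotropy -> EGGER",
                         pleiotropy$pval)
    chosen <- "EGGER"
  } else {
    rationale <- sprintf("Egger intercept p = %.3g >= 0.05: no directional pleiotropy",
                         pleiotropy$pval)
    if (het$i2 > 0.25 && het$pval < 0.05) {
      rationale <- c(rationale,
                     sprintf("I2 = %.1f%% > 25%% and Q p = %.3g < 0.05: heterogeneity -> IVW_RANDOM",
                             100 * het$i2, het$pval))
      chosen <- "IVW_RANDOM"
    } else {
      rationale <- c(rationale,
                     sprintf("I2 = %.1f%%, Q p = %.3g: no significant heterogeneity -> IVW_FIXED",
                             100 * het$i2, het$pval))
      chosen <- "IVW_FIXED"
    }
  }
  structure(list(chosen = chosen, pleiotropy_p = pleiotropy$pval,
                 q = het$Q, q_pval = het$pval, i2 = het$i2,
                 rationale = rationale),
            class = "mr_method_choice")
}

#' Choose the multivariable estimator from pleiotropy and heterogeneity
#'
#' MV-Egger when the multivariable intercept test is significant
#' (p < 0.05); otherwise QHET when there is significant heterogeneity
#' (I^2 > 25% and Q p < 0.05); otherwise multivariable IVW.
#'
#' @param mv_pleiotropy_p Multivariable Egger intercept p-value.
#' @param het Heterogeneity result (list with `Q`, `pval`, `i2`).
#' @return An `mr_method_choice` with `chosen` in
#'   `MV_EGGER`/`QHET`/`MV_IVW`.
#' @export
select_mvmr_method <- function(mv_pleiotropy_p, het) {
  rationale <- character(0)
  if (mv_pleiotropy_p < 0.05) {
    rationale <- sprintf("MV-Egger intercept p = %.3g < 0.05 -> MV_EGGER", mv_pleiotropy_p)
    chosen <- "MV_EGGER"
  } else {
    rationale <- sprintf("MV-Egger intercept p = %.3g >= 0.05: no pleiotropy", mv_pleiotropy_p)
    if (het$i2 > 0.25 && het$pval < 0.05) {
      rationale <- c(rationale, sprintf("I2 = %.1f%% > 25%% and Q p = %.3g < 0.05 -> QHET",
                                        100 * het$i2, het$pval))
      chosen <- "QHET"
    } else {
      rationale <- c(rationale, sprintf("I2 = %.1f%%, Q p = %.3g -> MV_IVW",
                                        100 * het$i2, het$pval))
      chosen <- "MV_IVW"
    }
  }
  structure(list(chosen = chosen, pleiotropy_p = mv_pleiotropy_p,
                 q = het$Q, q_pval = het$pval, i2 = het$i2,
                 rationale = rationale),
            class = "mr_method_choice")
}

#' @export
print.mr_method_choice <- function(x, ...) {
  cat("Method choice:", x$chosen, "\n")
  for (r in x$rationale) cat("  -", r, "\n")
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate q-values with monotonicity enforcement,
#' returned in the input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  p.adjust(pvals, method = "BH")
}

#' Tier a family of tests into significant / suggestive / null evidence
#'
#' Evidence is `SIGNIFICANT` when the BH q-value is below 0.05,
#' `SUGGESTIVE` when the uncorrected p is below 0.05 but the q-value is
#' not, and `NULL` otherwise. The family is the whole p-value vector.
#'
#' @param pvals Numeric vector of p-values (one family).
#' @return A tibble with columns `pval`, `qval`, `tier`.
#' @export
classify_evidence <- function(pvals) {
  q <- bh_fdr(pvals)
  tibble::tibble(
    pval = pvals, qval = q,
    tier = dplyr::case_when(q < 0.05 ~ "SIGNIFICANT",
                            pvals < 0.05 ~ "SUGGESTIVE",
                            TRUE ~ "NULL")
  )
}

# One univariable analysis: selection -> exclusions -> harmonisation ->
# diagnostics -> decision-tree estimate. Used by total_effect/step1 and the
# grid runner.
univariable_analysis <- function(exposure, outcome, settings = mr_settings(),
                                 blacklist = character(), ld = NULL,
                                 exposure_name = "exposure") {
  iv <- select_instruments(exposure, p_threshold = settings$p_threshold,
                           ld = ld, r2_max = settings$r2_max,
                           window_bp = settings$window_bp)
  iv <- apply_exclusions(iv, blacklist = blacklist,
                         outcome_ids = outcome$snp,
                         eaf_ambiguity_band = settings$eaf_band)
  report <- exclusion_report(iv)
  if (nrow(iv) == 0) abort("no instruments survive the exclusion filters")
  h <- harmonize_pair(iv, outcome, eaf_ambiguity_band = settings$eaf_band,
                      exposure_name = exposure_name)
  ivw_fixed <- mr_ivw(h, "fixed")
  if (nrow(h) >= 3) {
    eg <- mr_egger(h)
    het <- ivw_fixed$heterogeneity
    choice <- select_univariable_method(eg$pleiotropy, het)
    est <- switch(choice$chosen,
                  EGGER = eg$estimate,
                  IVW_RANDOM = mr_ivw(h, "random"),
                  IVW_FIXED = ivw_fixed)
  } else {
    eg <- NULL
    choice <- structure(list(chosen = ivw_fixed$method, pleiotropy_p = NA_real_,
                             q = NA_real_, q_pval = NA_real_, i2 = NA_real_,
                             rationale = "fewer than 3 SNPs: fixed-effect IVW by default"),
                        class = "mr_method_choice")
    est <- ivw_fixed
  }
  list(harmonized = h, estimate = est, choice = choice, egger = eg,
       exclusions = report, f = f_statistics(h))
}

#' Run the full exposure-by-outcome MR grid with FDR tiering and mediation
#'
#' For every exposure-outcome pair: instrument selection, exclusions,
#' harmonisation, the pleiotropy/heterogeneity decision tree and the chosen
#' estimate; then BH-FDR tiering over the whole family of total-effect
#' tests. Pairs whose total-effect p falls below the mediation trigger
#' (default uncorrected p < 0.05) additionally get the full two-step
#' mediation analysis through the mediator. Per-pair failures are recorded
#' and the run continues.
#'
#' @param exposures Named list of exposure summary-statistics tibbles.
#' @param outcomes Named list of outcome summary-statistics tibbles.
#' @param mediator Optional mediator summary-statistics tibble; `NULL`
#'   skips mediation.
#' @param settings An [mr_settings()] list.
#' @param blacklist Confounder-associated SNP ids to exclude.
#' @param ld Optional LD r^2 matrix.
#' @return A list of class `mr_grid`: `effects` (one row per pair with
#'   estimate, OR, diagnostics, tier), `mediation` (Table-2-style rows, one
#'   per mediated pair), `failures`, and `log` (decision trace).
#' @export
run_grid <- function(exposures, outcomes, mediator = NULL,
                     settings = mr_settings(), blacklist = character(),
                     ld = NULL) {
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1,
            !is.null(names(exposures)), !is.null(names(outcomes)))
  rows <- list(); failures <- list(); log <- list(); analyses <- list()
  for (ex in names(exposures)) {
    for (out in names(outcomes)) {
      pair <- paste(ex, out, sep = " -> ")
      res <- tryCatch(
        univariable_analysis(exposures[[ex]], outcomes[[out]], settings,
                             blacklist, ld, exposure_name = ex),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[pair]] <- conditionMessage(res)
        log[[length(log) + 1]] <- tibble::tibble(
          pair = pair, event = "failure", detail = conditionMessage(res))
        next
      }
      analyses[[pair]] <- res
      e <- res$estimate
      rows[[pair]] <- tibble::tibble(
        exposure = ex, outcome = out, method = e$method, n_snp = e$n_snp,
        beta = e$beta, se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
        or = exp(e$beta), or_low = exp(e$ci_low), or_high = exp(e$ci_high),
        pval = e$pval,
        pleiotropy_p = res$choice$pleiotropy_p,
        q = res$choice$q, q_pval = res$choice$q_pval, i2 = res$choice$i2,
        mean_f = res$f$mean_f,
        n_input = res$exclusions$n_input, n_retained = res$exclusions$n_retained
      )
      log[[length(log) + 1]] <- tibble::tibble(
        pair = pair, event = "method_choice",
        detail = paste(res$choice$rationale, collapse = " | "))
    }
  }
  effects <- dplyr::bind_rows(rows)
  if (nrow(effects) > 0) {
    tiers <- classify_evidence(effects$pval)
    effects$qval <- tiers$qval
    effects$tier <- tiers$tier
  }

  mediation_rows <- list()
  if (!is.null(mediator) && nrow(effects) > 0) {
    triggered <- effects[effects$pval < settings$mediation_trigger_p, ]
    for (i in seq_len(nrow(triggered))) {
      ex <- triggered$exposure[i]; out <- triggered$outcome[i]
      pair <- paste(ex, out, sep = " -> ")
      med <- tryCatch(
        run_mediation(exposures[[ex]], mediator, outcomes[[out]],
                      settings = settings, blacklist = blacklist, ld = ld,
                      exposure_name = ex, outcome_name = out),
        error = function(e) e)
      if (inherits(med, "error")) {
        failures[[paste0(pair, " [mediation]")]] <- conditionMessage(med)
        log[[length(log) + 1]] <- tibble::tibble(
          pair = pair, event = "mediation_failure", detail = conditionMessage(med))
        next
      }
      mediation_rows[[pair]] <- tidy(med)
      log[[length(log) + 1]] <- tibble::tibble(
        pair = pair, event = "mediation",
        detail = paste0("step2 method: ", med$step2_method))
    }
  }
  mediation_tbl <- dplyr::bind_rows(mediation_rows)
  if (nrow(mediation_tbl) > 0) {
    mediation_tbl$sobel_q <- bh_fdr(mediation_tbl$sobel_p)
  }

  structure(list(effects = effects, mediation = mediation_tbl,
                 failures = failures, log = dplyr::bind_rows(log),
                 analyses = analyses, settings = settings),
            class = "mr_grid")
}

#' @export
print.mr_grid <- function(x, ...) {
  cat("MR grid:", nrow(x$effects), "pair(s),",
      sum(x$effects$tier == "SIGNIFICANT"), "significant,",
      sum(x$effects$tier == "SUGGESTIVE"), "suggestive;",
      length(x$failures), "failure(s);",
      nrow(x$mediation), "mediated pair(s)\n")
  invisible(x)
}

#' Write the grid report tables to a directory
#'
#' Emits `effects.tsv` (one row per exposure-outcome pair, forest-plot
#' style), `mediation.tsv` (Table-2-style mediation rows) and `run_log.tsv`
#' (the machine-readable decision trace).
#'
#' @param grid An `mr_grid` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_grid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(grid$effects, file.path(dir, "effects.tsv"), progress = FALSE)
  if (nrow(grid$mediation) > 0) {
    readr::write_tsv(grid$mediation, file.path(dir, "mediation.tsv"), progress = FALSE)
  }
  readr::write_tsv(grid$log, file.path(dir, "run_log.tsv"), progress = FALSE)
  invisible(dir)
}
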