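#' Configuration for the mediation-DAG summary-statistics generator
#'
#' Describes the exposure -> mediator -> outcome causal diagram and the
#' three independent GWAS samples the generator emulates. Defaults mirror a
#' biobank-scale two-sample design: a few hundred thousand samples per
#' study, instruments with mean F around 30 (adequate power for modest
#' effects), genome-wide-significance selection of the exposure study at
#' 5e-8, and no pleiotropy.
#'
#' @param n_snp Number of candidate SNPs.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param maf_range Minor-allele-frequency range, inside (0, 0.5].
#' @param theta_direct Direct exposure -> outcome effect (log-odds per
#'   unit exposure).
#' @param beta_a_true Exposure -> mediator effect.
#' @param beta_b_true Mediator -> outcome effect.
#' @param prop_mediator_snp Fraction of SNPs that instrument the mediator
#'   directly (needed to identify the mediator coefficient in
#'   multivariable MR); the rest instrument the exposure.
#' @param f_mean_target Target mean instrument F statistic in the study a
#'   SNP instruments.
#' @param pleiotropy_mode `"NONE"`, `"BALANCED"` (zero-mean direct outcome
#'   effects) or `"DIRECTIONAL"` (mean `pleiotropy_mean`).
#' @param pleiotropy_sd SD of the pleiotropic effects.
#' @param pleiotropy_mean Mean pleiotropic effect (directional mode).
#' @param prop_invalid Fraction of SNPs carrying pleiotropy.
#' @param palindrome_fraction Fraction of SNPs given A/T or C/G alleles.
#' @param selection_p Significance threshold applied to the exposure and
#'   mediator studies before release (1 disables selection).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snp = 100,
                       n_exposure = 250000, n_mediator = 170000,
                       n_outcome = 200000,
                       maf_range = c(0.05, 0.5),
                       theta_direct = 0.1, beta_a_true = 0.5,
                       beta_b_true = 0.2,
                       prop_mediator_snp = 0.5,
                       f_mean_target = 30,
                       pleiotropy_mode = c("NONE", "BALANCED", "DIRECTIONAL"),
                       pleiotropy_sd = 0.01, pleiotropy_mean = 0.01,
                       prop_invalid = 0, palindrome_fraction = 0.2,
                       selection_p = 5e-8, seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snp > 0, n_exposure > 0, n_mediator > 0, n_outcome > 0,
            maf_range[1] > 0, maf_range[1] <= maf_range[2], maf_range[2] <= 0.5,
            prop_invalid >= 0, prop_invalid <= 1,
            prop_mediator_snp >= 0, prop_mediator_snp <= 1,
            palindrome_fraction >= 0, palindrome_fraction <= 1,
            selection_p > 0, selection_p <= 1, f_mean_target > 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate two-sample GWAS summary statistics under a mediation DAG
#'
#' Generates three independent summary-statistics tables (exposure,
#' mediator, outcome studies) from the causal diagram
#' exposure -> mediator -> outcome with a direct exposure -> outcome path.
#' Per-SNP true effects: exposure instruments carry `xi_j` on the exposure,
#' `beta_a * xi_j` on the mediator and
#' `(theta_direct + beta_a * beta_b) * xi_j` on the outcome;
#' mediator-specific instruments carry `eta_j` on the mediator and
#' `beta_b * eta_j` on the outcome. Invalid SNPs add pleiotropic outcome
#' (and mediator) effects drawn per `pleiotropy_mode`. Standard errors
#' follow the analytic per-allele form `1/sqrt(2 maf (1 - maf) n)`;
#' observed effects are the true effects plus independent study noise. The
#' exposure and mediator studies are filtered at `selection_p` (emulating
#' instrument discovery), everything is seed-deterministic.
#'
#' @param cfg A [sim_config()] list.
#' @return A list with tibbles `exposure`, `mediator`, `outcome` and
#'   `truth` — a `sim_truth` list holding the generating parameters,
#'   `theta_total`, `proportion_true` and the per-SNP draws.
#' @export
simulate_mediation_dag <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_snp
  maf <- runif(n, cfg$maf_range[1], cfg$maf_range[2])
  se_of <- function(n_study) 1 / sqrt(2 * maf * (1 - maf) * n_study)
  sex <- se_of(cfg$n_exposure)
  sem <- se_of(cfg$n_mediator)
  sey <- se_of(cfg$n_outcome)

  is_med_snp <- seq_len(n) <= round(n * cfg$prop_mediator_snp)
  is_med_snp <- sample(is_med_snp)
  # instrument effects scaled so the mean F in the instrumented study hits
  # the target: E[(b/se)^2] = 1 + var(effect)/se^2
  sd_xi <- sqrt((cfg$f_mean_target - 1) / mean(1 / sex^2))
  sd_eta <- sqrt((cfg$f_mean_target - 1) / mean(1 / sem^2))
  xi <- ifelse(is_med_snp, 0, rnorm(n, 0, sd_xi))
  eta <- ifelse(is_med_snp, rnorm(n, 0, sd_eta), 0)

  invalid <- runif(n) < cfg$prop_invalid
  pl_mean <- switch(cfg$pleiotropy_mode, NONE = 0, BALANCED = 0,
                    DIRECTIONAL = cfg$pleiotropy_mean)
  pl_sd <- if (cfg$pleiotropy_mode == "NONE") 0 else cfg$pleiotropy_sd
  # pleiotropic effects are defined relative to the trait-increasing allele
  # (orientation sign), so DIRECTIONAL mode biases allele-agnostic estimators
  orient <- sign(xi + eta)
  orient[orient == 0] <- 1
  alpha <- ifelse(invalid, rnorm(n, pl_mean, pl_sd), 0) * orient  # mediator path
  gamma <- ifelse(invalid, rnorm(n, pl_mean, pl_sd), 0) * orient  # outcome path

  theta_total <- cfg$theta_direct + cfg$beta_a_true * cfg$beta_b_true
  true_bx <- xi
  true_bm <- cfg$beta_a_true * xi + eta + alpha
  true_by <- theta_total * xi + cfg$beta_b_true * eta + gamma

  bx <- rnorm(n, true_bx, sex)
  bm <- rnorm(n, true_bm, sem)
  by <- rnorm(n, true_by, sey)

  # alleles: palindromic fraction gets A/T or C/G pairs
  pal <- runif(n) < cfg$palindrome_fraction
  pair_idx <- sample.int(2, n, replace = TRUE)
  ea <- ifelse(pal, c("A", "C")[pair_idx], c("A", "C")[pair_idx])
  oa <- ifelse(pal, c("T", "G")[pair_idx], c("G", "T")[pair_idx])
  eaf <- maf

  chrom <- as.character(sample.int(22, n, replace = TRUE))
  pos <- sample.int(2.5e8, n)

  mk <- function(beta, se, n_study) {
    tibble::tibble(
      snp = paste0("rs", seq_len(n)), chr = chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = beta, se = se,
      pval = pmax(two_sided_p(beta / se), .Machine$double.xmin),
      n = n_study)
  }
  exposure <- mk(bx, sex, cfg$n_exposure)
  mediator <- mk(bm, sem, cfg$n_mediator)
  outcome <- mk(by, sey, cfg$n_outcome)

  keep_exp <- exposure$pval < cfg$selection_p | is_med_snp
  keep_med <- mediator$pval < cfg$selection_p | !is_med_snp
  if (!any(exposure$pval[!is_med_snp] < cfg$selection_p)) {
    abort(paste0("no exposure SNP survives selection at p < ", cfg$selection_p,
                 "; increase f_mean_target or the sample size"))
  }
  exposure <- exposure[keep_exp, ]
  mediator <- mediator[keep_med, ]

  truth <- structure(
    list(config = cfg, theta_total = theta_total,
         proportion_true = 100 * cfg$beta_a_true * cfg$beta_b_true / theta_total,
         snp = paste0("rs", seq_len(n)), xi = xi, eta = eta,
         alpha = alpha, gamma = gamma, invalid = invalid,
         is_mediator_snp = is_med_snp, maf = maf, seed = cfg$seed),
    class = "sim_truth")
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: theta_direct = %.3f, beta_a = %.3f, beta_b = %.3f\n",
              x$config$theta_direct, x$config$beta_a_true, x$config$beta_b_true))
  cat(sprintf("  theta_total = %.4f, proportion mediated = %.2f%%, seed = %d\n",
              x$theta_total, x$proportion_true, x$seed))
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Writes `exposure.tsv`, `mediator.tsv`, `outcome.tsv` plus the generating
#' truth and configuration as `truth.txt` (key=value).
#'
#' @param sim Output of [simulate_mediation_dag()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  tr <- sim$truth
  cfg <- tr$config
  keys <- c(theta_direct = cfg$theta_direct, beta_a_true = cfg$beta_a_true,
            beta_b_true = cfg$beta_b_true, theta_total = tr$theta_total,
            proportion_true = tr$proportion_true, seed = cfg$seed,
            n_snp = cfg$n_snp, selection_p = cfg$selection_p,
            f_mean_target = cfg$f_mean_target,
            prop_invalid = cfg$prop_invalid)
  writeLines(paste0(names(keys), "=", keys), file.path(dir, "truth.txt"))
  invisible(dir)
}

#' Benchmark estimators over a grid of simulation scenarios
#'
#' Repeats simulate -> harmonise -> estimate `n_reps` times per scenario
#' and tabulates mean bias, empirical SE, mean model SE, 95% CI coverage of
#' the true total effect and rejection rate at alpha = 0.05.
#'
#' @param scenarios A list of [sim_config()] objects (names become labels).
#' @param estimators Character vector of estimators to run, any of
#'   `"ivw_fixed"`, `"ivw_random"`, `"egger"`, `"wmedian"`, `"ml"`,
#'   `"radial"`.
#' @param n_reps Replicates per scenario.
#' @param seed Base seed; replicate r of scenario s uses
#'   `seed + 1000 * s + r`.
#' @return A tibble with one row per scenario x estimator.
#' @export
mr_benchmark <- function(scenarios, estimators = c("ivw_fixed", "egger"),
                         n_reps = 100, seed = 1) {
  if (is.null(names(scenarios))) names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  fit_one <- function(h, est) {
    switch(est,
           ivw_fixed = mr_ivw(h, "fixed"),
           ivw_random = mr_ivw(h, "random"),
           egger = mr_egger(h)$estimate,
           wmedian = mr_weighted_median(h, n_boot = 100),
           ml = mr_max_likelihood(h),
           radial = mr_radial_ivw(h),
           abort(paste0("unknown estimator: ", est)))
  }
  rows <- list()
  for (s in seq_along(scenarios)) {
    cfg <- scenarios[[s]]
    res <- purrr::map(seq_len(n_reps), function(r) {
      cfg$seed <- seed + 1000 * s + r
      sim <- simulate_mediation_dag(cfg)
      # univariable benchmarking instruments the exposure only
      expo <- sim$exposure[sim$exposure$snp %in%
                             sim$truth$snp[!sim$truth$is_mediator_snp], ]
      h <- harmonize_pair(expo, sim$outcome, exposure_name = "exposure")
      truth <- sim$truth$theta_total
      purrr::map(setNames(estimators, estimators), function(est) {
        e <- tryCatch(fit_one(h, est), error = function(err) NULL)
        if (is.null(e)) return(NULL)
        tibble::tibble(beta = e$beta, se = e$se,
                       covered = e$ci_low <= truth & truth <= e$ci_high,
                       rejected = e$pval < 0.05)
      })
    })
    for (est in estimators) {
      tab <- dplyr::bind_rows(purrr::map(res, est))
      truth <- scenarios[[s]]$theta_direct +
        scenarios[[s]]$beta_a_true * scenarios[[s]]$beta_b_true
      rows[[paste(s, est)]] <- tibble::tibble(
        scenario = names(scenarios)[s], estimator = est,
        n_reps = nrow(tab),
        bias = mean(tab$beta) - truth,
        empirical_se = sd(tab$beta),
        mean_model_se = mean(tab$se),
        coverage = mean(tab$covered),
        rejection = mean(tab$rejected))
    }
  }
  dplyr::bind_rows(rows)
}
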