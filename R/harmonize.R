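#' @title Harmonised instrument sets
#' @description A harmonised set (class `mr_harm`) is a tibble with one row
#' per retained SNP and columns `snp`, `effect_allele`, `other_allele`,
#' `eaf`, per-exposure aligned effects `bx_1`/`sex_1` (and `bx_2`/`sex_2`
#' for multivariable sets), outcome effects `by`/`sey`, and a `flags` column
#' recording every harmonisation action. The exposure names live in the
#' `exposure_names` attribute and dropped SNPs (with reasons) in `dropped`.
#' @name mr_harm
NULL

new_mr_harm <- function(tbl, exposure_names, dropped) {
  structure(tbl,
            exposure_names = exposure_names,
            dropped = dropped,
            class = c("mr_harm", class(tibble::as_tibble(tbl))))
}

#' @export
print.mr_harm <- function(x, ...) {
  cat("Harmonised set:", nrow(x), "SNPs,",
      length(attr(x, "exposure_names")), "exposure(s):",
      paste(attr(x, "exposure_names"), collapse = ", "), "\n")
  NextMethod()
}

#' Number of exposures in a harmonised set
#' @param h An `mr_harm` object.
#' @return Integer count of exposures.
#' @export
n_exposures <- function(h) length(attr(h, "exposure_names"))

#' Exposure-effect matrix of a harmonised set
#' @param h An `mr_harm` object.
#' @param what `"beta"` or `"se"`.
#' @return A numeric matrix, SNPs by exposures.
#' @export
harm_bx <- function(h, what = c("beta", "se")) {
  what <- match.arg(what)
  k <- n_exposures(h)
  cols <- paste0(if (what == "beta") "bx_" else "sex_", seq_len(k))
  m <- as.matrix(tibble::as_tibble(h)[, cols])
  colnames(m) <- attr(h, "exposure_names")
  m
}

# Align one study's association to the target (exposure) allele pair.
# Returns list(beta, se, flag) or NULL when irreconcilable/ambiguous.
align_to_target <- function(t_ea, t_oa, t_eaf, s_ea, s_oa, s_eaf, s_beta, s_se,
                            band) {
  pal <- is_palindromic(t_ea, t_oa)
  if (pal) {
    # strand is undecidable from alleles; use frequency concordance
    if (is.na(t_eaf) || is.na(s_eaf) ||
        (t_eaf > band[1] && t_eaf < band[2]) ||
        (s_eaf > band[1] && s_eaf < band[2])) {
      return(NULL)
    }
    if (!((s_ea == t_ea && s_oa == t_oa) || (s_ea == t_oa && s_oa == t_ea))) {
      return(NULL)
    }
    same_side <- (t_eaf < 0.5) == (s_eaf < 0.5)
    oriented_same <- s_ea == t_ea
    if (oriented_same == same_side) {
      if (oriented_same) list(beta = s_beta, se = s_se, flag = "ok")
      else list(beta = -s_beta, se = s_se, flag = "swap")
    } else {
      # frequencies disagree with the label orientation: flip
      if (oriented_same) list(beta = -s_beta, se = s_se, flag = "pal_freq_flip")
      else list(beta = s_beta, se = s_se, flag = "pal_freq_keep")
    }
  } else if (s_ea == t_ea && s_oa == t_oa) {
    list(beta = s_beta, se = s_se, flag = "ok")
  } else if (s_ea == t_oa && s_oa == t_ea) {
    list(beta = -s_beta, se = s_se, flag = "swap")
  } else {
    c_ea <- unname(complement_allele(s_ea))
    c_oa <- unname(complement_allele(s_oa))
    if (c_ea == t_ea && c_oa == t_oa) {
      list(beta = s_beta, se = s_se, flag = "strand")
    } else if (c_ea == t_oa && c_oa == t_ea) {
      list(beta = -s_beta, se = s_se, flag = "strand_swap")
    } else {
      NULL
    }
  }
}

#' Harmonise exposure and outcome summary statistics to one effect allele
#'
#' For every SNP shared between the two studies, aligns the outcome effect
#' to the exposure's effect allele: matching alleles are copied, swapped
#' alleles negate the outcome beta (and reflect its frequency), and alleles
#' that match only after strand complementation are complemented first.
#' Palindromic SNPs (A/T, C/G) are resolved by effect-allele-frequency
#' concordance and dropped when either frequency is missing or lies inside
#' the ambiguity band. SNPs whose alleles cannot be reconciled are dropped
#' with a flag, never an error.
#'
#' @param exposure,outcome Summary-statistics tibbles.
#' @param eaf_ambiguity_band Open interval of ambiguous palindrome
#'   frequencies, default `c(0.42, 0.58)`.
#' @param exposure_name Label stored in the result.
#'
#' @return An [mr_harm] tibble with one exposure (`bx_1`, `sex_1`).
#' @export
harmonize_pair <- function(exposure, outcome, eaf_ambiguity_band = c(0.42, 0.58),
                           exposure_name = "exposure") {
  exposure <- tibble::as_tibble(exposure)
  outcome <- tibble::as_tibble(outcome)
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0) abort("no SNPs shared between exposure and outcome")
  ei <- match(shared, exposure$snp)
  oi <- match(shared, outcome$snp)

  rows <- vector("list", length(shared))
  dropped <- list()
  for (k in seq_along(shared)) {
    e <- exposure[ei[k], ]; o <- outcome[oi[k], ]
    al <- align_to_target(e$effect_allele, e$other_allele, e$eaf,
                          o$effect_allele, o$other_allele, o$eaf,
                          o$beta, o$se, eaf_ambiguity_band)
    if (is.null(al)) {
      reason <- if (is_palindromic(e$effect_allele, e$other_allele))
        "palindrome_ambiguous" else "alleles_irreconcilable"
      dropped[[length(dropped) + 1]] <- tibble::tibble(snp = e$snp, reason = reason)
      next
    }
    rows[[k]] <- tibble::tibble(
      snp = e$snp, effect_allele = e$effect_allele, other_allele = e$other_allele,
      eaf = e$eaf, bx_1 = e$beta, sex_1 = e$se, by = al$beta, sey = al$se,
      flags = al$flag
    )
  }
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) == 0) abort("harmonisation dropped every shared SNP")
  new_mr_harm(tbl, exposure_name,
              dropped = dplyr::bind_rows(dropped))
}

#' Harmonise exposure, mediator and outcome studies for multivariable MR
#'
#' Takes the union of the exposure's and the mediator's univariable
#' instrument lists, de-duplicates it, optionally re-prunes for mutual LD
#' (greedy, by the smaller of the two studies' p-values), then aligns the
#' mediator and outcome effects of every SNP to the exposure study's effect
#' allele. SNPs missing from any of the three studies, or with
#' irreconcilable or ambiguous alleles, are dropped with flags.
#'
#' @param exposure,mediator,outcome Full summary-statistics tibbles.
#' @param iv_exposure,iv_mediator Instrument tibbles from
#'   [select_instruments()] on the exposure and mediator studies.
#' @param ld Optional r^2 matrix for mutual re-pruning of the union.
#' @param r2_max LD threshold used when `ld` is given.
#' @param eaf_ambiguity_band Palindrome ambiguity band.
#' @param exposure_names Length-2 labels, default
#'   `c("exposure", "mediator")`.
#'
#' @return An [mr_harm] tibble with two exposures (`bx_1/sex_1` = exposure,
#'   `bx_2/sex_2` = mediator).
#' @export
harmonize_multi <- function(exposure, mediator, outcome,
                            iv_exposure, iv_mediator,
                            ld = NULL, r2_max = 0.01,
                            eaf_ambiguity_band = c(0.42, 0.58),
                            exposure_names = c("exposure", "mediator")) {
  union_ids <- union(iv_exposure$snp, iv_mediator$snp)
  if (length(union_ids) == 0) abort("empty instrument union for multivariable MR")

  # best available selection p-value per SNP, used for greedy LD re-pruning
  pmin_tbl <- dplyr::bind_rows(
    dplyr::select(tibble::as_tibble(iv_exposure), "snp", "pval"),
    dplyr::select(tibble::as_tibble(iv_mediator), "snp", "pval")
  ) |>
    dplyr::group_by(.data$snp) |>
    dplyr::summarise(pval = min(.data$pval), .groups = "drop") |>
    dplyr::arrange(.data$pval, .data$snp)

  ids <- pmin_tbl$snp
  if (!is.null(ld)) {
    keep <- character(0)
    for (s in ids) {
      if (!s %in% rownames(ld)) { keep <- c(keep, s); next }
      in_ld <- any(vapply(keep[keep %in% rownames(ld)],
                          function(t) ld[s, t] >= r2_max, logical(1)))
      if (!in_ld) keep <- c(keep, s)
    }
    ids <- keep
  }

  exposure <- tibble::as_tibble(exposure)
  mediator <- tibble::as_tibble(mediator)
  outcome <- tibble::as_tibble(outcome)

  rows <- list(); dropped <- list()
  for (s in ids) {
    ei <- match(s, exposure$snp)
    mi <- match(s, mediator$snp)
    oi <- match(s, outcome$snp)
    if (is.na(ei) || is.na(mi) || is.na(oi)) {
      miss <- c("exposure", "mediator", "outcome")[c(is.na(ei), is.na(mi), is.na(oi))]
      dropped[[length(dropped) + 1]] <-
        tibble::tibble(snp = s, reason = paste0("missing_in_", paste(miss, collapse = "+")))
      next
    }
    e <- exposure[ei, ]
    alm <- align_to_target(e$effect_allele, e$other_allele, e$eaf,
                           mediator$effect_allele[mi], mediator$other_allele[mi],
                           mediator$eaf[mi], mediator$beta[mi], mediator$se[mi],
                           eaf_ambiguity_band)
    alo <- align_to_target(e$effect_allele, e$other_allele, e$eaf,
                           outcome$effect_allele[oi], outcome$other_allele[oi],
                           outcome$eaf[oi], outcome$beta[oi], outcome$se[oi],
                           eaf_ambiguity_band)
    if (is.null(alm) || is.null(alo)) {
      dropped[[length(dropped) + 1]] <-
        tibble::tibble(snp = s, reason = "alleles_irreconcilable_or_ambiguous")
      next
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      snp = s, effect_allele = e$effect_allele, other_allele = e$other_allele,
      eaf = e$eaf,
      bx_1 = e$beta, sex_1 = e$se,
      bx_2 = alm$beta, sex_2 = alm$se,
      by = alo$beta, sey = alo$se,
      flags = paste(alm$flag, alo$flag, sep = ";")
    )
  }
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) == 0) abort("multivariable harmonisation retained no SNPs")
  new_mr_harm(tbl, exposure_names, dropped = dplyr::bind_rows(dropped))
}

#' Construct a harmonised set directly from aligned effect vectors
#'
#' Convenience constructor for simulation studies and tests where alleles
#' are already aligned.
#'
#' @param bx,sex Exposure effects and SEs: vectors (one exposure) or
#'   matrices with one column per exposure.
#' @param by,sey Outcome effects and SEs.
#' @param snp Optional SNP ids.
#' @param exposure_names Optional exposure labels.
#' @return An [mr_harm] tibble.
#' @export
as_mr_harm <- function(bx, sex, by, sey, snp = NULL, exposure_names = NULL) {
  bx <- as.matrix(bx); sex <- as.matrix(sex)
  k <- ncol(bx)
  stopifnot(ncol(sex) == k, nrow(bx) == length(by), length(by) == length(sey),
            all(sex > 0), all(sey > 0))
  if (is.null(snp)) snp <- paste0("rs", seq_along(by))
  if (is.null(exposure_names)) {
    exposure_names <- if (k == 1) "exposure" else paste0("exposure_", seq_len(k))
  }
  tbl <- tibble::tibble(snp = snp,
                        effect_allele = "A", other_allele = "G", eaf = NA_real_)
  for (i in seq_len(k)) {
    tbl[[paste0("bx_", i)]] <- bx[, i]
    tbl[[paste0("sex_", i)]] <- sex[, i]
  }
  tbl$by <- by; tbl$sey <- sey; tbl$flags <- "ok"
  new_mr_harm(tbl, exposure_names, dropped = tibble::tibble(snp = character(),
                                                            reason = character()))
}

#' Serialise a harmonised set as TSV
#' @param h An [mr_harm] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path) {
  readr::write_tsv(tibble::as_tibble(h), path, progress = FALSE)
  invisible(path)
}
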