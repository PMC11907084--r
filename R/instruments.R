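#' Select approximately independent genome-wide-significant instruments
#'
#' Keeps SNPs with `pval < p_threshold` and greedily prunes them for
#' independence: candidates are visited in ascending p-value order and a SNP
#' is kept unless its LD r^2 with an already-kept SNP is >= `r2_max` (when an
#' LD matrix is supplied) or, failing that, it lies within `window_bp` of a
#' kept SNP on the same chromosome (closed window, 1-based coordinates).
#' Ties in p-value are broken by SNP id so the result does not depend on the
#' input row order.
#'
#' @param assocs Summary-statistics tibble (see [read_sumstats()]).
#' @param p_threshold Significance threshold in (0, 1).
#' @param ld Optional square r^2 matrix with SNP-id dimnames.
#' @param r2_max Maximum tolerated pairwise r^2 (default 0.01).
#' @param window_bp Distance window in base pairs (default 1 Mb).
#'
#' @return The retained rows, ordered by ascending p-value.
#' @export
select_instruments <- function(assocs, p_threshold = 5e-8, ld = NULL,
                               r2_max = 0.01, window_bp = 1e6) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  assocs <- tibble::as_tibble(assocs)
  cand <- dplyr::filter(assocs, .data$pval < p_threshold)
  if (nrow(cand) == 0) {
    abort("no SNP passes the instrument p-value threshold (empty instrument set)")
  }
  cand <- dplyr::arrange(cand, .data$pval, .data$snp)
  if (!is.null(ld)) {
    missing_ids <- setdiff(cand$snp, rownames(ld))
    if (length(missing_ids)) {
      abort(paste0("LD matrix lacks SNP(s): ", paste(head(missing_ids, 5), collapse = ", ")))
    }
  }
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in kept) {
      if (!is.null(ld)) {
        if (ld[cand$snp[i], cand$snp[j]] >= r2_max) { ok <- FALSE; break }
      } else if (!is.na(cand$pos[i]) && !is.na(cand$pos[j]) &&
                 !is.na(cand$chr[i]) && !is.na(cand$chr[j]) &&
                 cand$chr[i] == cand$chr[j] &&
                 abs(cand$pos[i] - cand$pos[j]) <= window_bp) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  cand[kept, ]
}

#' Apply pre-harmonisation exclusion filters
#'
#' Drops instruments in a fixed precedence order so that each SNP is counted
#' in exactly one category: (1) SNPs on the confounder blacklist, (2) SNPs
#' absent from the outcome study, (3) palindromic SNPs (A/T or C/G allele
#' pairs) whose effect-allele frequency falls inside the ambiguity band or is
#' missing. The attached report reconciles exactly to the input count.
#'
#' @param assocs Summary-statistics tibble of candidate instruments.
#' @param blacklist Character vector of SNP ids associated with confounders.
#' @param outcome_ids Character vector of SNP ids present in the outcome
#'   study; `NULL` skips the missingness filter.
#' @param eaf_ambiguity_band Length-2 numeric `(lo, hi)` with 0 < lo < hi < 1.
#'
#' @return The retained rows with an `exclusion_report` attribute (a tibble
#'   of category counts; see [exclusion_report()]).
#' @export
apply_exclusions <- function(assocs, blacklist = character(),
                             outcome_ids = NULL,
                             eaf_ambiguity_band = c(0.42, 0.58)) {
  lo <- eaf_ambiguity_band[1]; hi <- eaf_ambiguity_band[2]
  stopifnot(lo > 0, lo < hi, hi < 1)
  assocs <- tibble::as_tibble(assocs)

  is_black <- assocs$snp %in% blacklist
  is_missing <- if (is.null(outcome_ids)) rep(FALSE, nrow(assocs)) else
    !assocs$snp %in% outcome_ids
  pal <- is_palindromic(assocs$effect_allele, assocs$other_allele)
  ambiguous <- pal & (is.na(assocs$eaf) | (assocs$eaf > lo & assocs$eaf < hi))

  # first applicable rule wins
  drop_black <- is_black
  drop_missing <- !drop_black & is_missing
  drop_pal <- !drop_black & !drop_missing & ambiguous
  retained <- !(drop_black | drop_missing | drop_pal)

  report <- tibble::tibble(
    n_input = nrow(assocs),
    n_blacklisted = sum(drop_black),
    n_missing_in_outcome = sum(drop_missing),
    n_palindromic_dropped = sum(drop_pal),
    n_outlier_dropped = 0L,
    n_retained = sum(retained)
  )
  out <- assocs[retained, ]
  attr(out, "exclusion_report") <- report
  out
}

#' Retrieve the exclusion report attached by [apply_exclusions()]
#'
#' @param x Output of [apply_exclusions()].
#' @return A one-row tibble of counts.
#' @export
exclusion_report <- function(x) attr(x, "exclusion_report")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complement_allele <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}

#' Per-SNP instrument-strength F statistics
#'
#' Computes the squared z statistic F_j = (bx_j / se_j)^2 for each SNP in a
#' single-exposure harmonised set, plus their mean — the conventional report
#' for the relevance assumption. No filtering is performed.
#'
#' @param h A harmonised set with one exposure (see [harmonize_pair()]).
#' @return A list with `per_snp` (tibble of snp, f) and `mean_f`.
#' @export
f_statistics <- function(h) {
  stopifnot(inherits(h, "mr_harm"), length(attr(h, "exposure_names")) == 1)
  f <- (h$bx_1 / h$sex_1)^2
  list(per_snp = tibble::tibble(snp = h$snp, f = f), mean_f = mean(f))
}
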