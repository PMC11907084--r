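#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads one association record per SNP from a header-ed TSV. Column names
#' can be remapped via `column_map`, a named character vector whose names are
#' the canonical fields (`snp`, `chr`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`) and whose values are the column names in
#' the file. Unmapped extra columns are ignored (with a message). Alleles are
#' upper-cased. Rows violating the basic invariants (se <= 0, p outside
#' (0, 1], eaf outside (0, 1), identical alleles) raise an error naming the
#' offending row.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Named character vector remapping canonical field names
#'   to file column names; only the fields that differ need to be given.
#'
#' @return A tibble with columns `snp`, `chr`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n` (optional fields are
#'   `NA` when absent from the file).
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort(paste0("summary-statistics file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  map <- c(snp = "snp", chr = "chr", pos = "pos",
           effect_allele = "effect_allele", other_allele = "other_allele",
           eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n")
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(map))
    if (length(bad)) abort(paste0("unknown field(s) in column_map: ",
                                  paste(bad, collapse = ", ")))
    map[names(column_map)] <- column_map
  }
  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- map[mandatory][!map[mandatory] %in% names(raw)]
  if (length(missing_cols)) {
    abort(paste0("mandatory column(s) missing from ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(raw), unname(map))
  if (length(extra)) {
    inform(paste0("ignoring unmapped column(s): ", paste(extra, collapse = ", ")))
  }

  get_col <- function(field, parser = identity) {
    col <- map[[field]]
    if (col %in% names(raw)) parser(raw[[col]]) else rep(NA, nrow(raw))
  }
  parse_num <- function(field) {
    col <- map[[field]]
    if (!col %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(x))
    if (length(bad)) {
      abort(paste0("unparsable numeric in column '", col, "' at data row ",
                   bad[1], ": '", raw[[col]][bad[1]], "'"))
    }
    x
  }

  out <- tibble::tibble(
    snp = as.character(get_col("snp")),
    chr = as.character(get_col("chr")),
    pos = parse_num("pos"),
    effect_allele = toupper(as.character(get_col("effect_allele"))),
    other_allele = toupper(as.character(get_col("other_allele"))),
    eaf = parse_num("eaf"),
    beta = parse_num("beta"),
    se = parse_num("se"),
    pval = parse_num("pval"),
    n = parse_num("n")
  )
  validate_sumstats(out, context = path)
}

#' Validate a summary-statistics table
#'
#' Checks the per-row invariants of an association record: alleles in
#' {A,C,G,T} and distinct, se > 0, p in (0, 1], eaf (if present) strictly
#' inside (0, 1). Invalid rows raise an error naming the first offending row.
#'
#' @param x A data frame of associations (as from [read_sumstats()]).
#' @param context Label used in error messages.
#' @return `x` as a tibble, invisibly validated.
#' @export
validate_sumstats <- function(x, context = "sumstats") {
  x <- tibble::as_tibble(x)
  fail <- function(i, what) {
    abort(paste0(context, ": row ", i, " (", x$snp[i], "): ", what))
  }
  bases <- c("A", "C", "G", "T")
  chk <- function(cond, what) {
    i <- which(cond)
    if (length(i)) fail(i[1], what)
  }
  chk(!x$effect_allele %in% bases | !x$other_allele %in% bases,
      "alleles must be single bases A/C/G/T")
  chk(x$effect_allele == x$other_allele, "effect and other allele identical")
  chk(is.na(x$se) | x$se <= 0, "standard error must be > 0")
  chk(is.na(x$beta), "beta missing")
  chk(is.na(x$pval) | x$pval <= 0 | x$pval > 1, "p-value must lie in (0, 1]")
  chk(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1),
      "effect-allele frequency must lie strictly in (0, 1)")
  x
}

#' Write summary statistics to a tab-delimited file
#'
#' @param x Summary-statistics tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Read a square LD matrix of r-squared values
#'
#' Expects a tab-separated file whose first column and header row carry SNP
#' identifiers; the body is a symmetric matrix of r^2 values in [0, 1].
#'
#' @param path Path to the matrix file.
#' @return A numeric matrix with SNP ids as dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!identical(sort(ids), sort(colnames(m)))) {
    abort("LD matrix header and first column must list the same SNP ids")
  }
  m <- m[ids, ids]
  if (any(m < 0 | m > 1, na.rm = TRUE)) abort("LD r^2 values must lie in [0, 1]")
  m
}

#' Read a SNP blacklist (one identifier per line)
#'
#' @param path Path to a plain-text file, one SNP id per line; blank lines
#'   and lines starting with `#` are skipped.
#' @return Character vector of SNP ids.
#' @export
read_blacklist <- function(path) {
  lines <- trimws(readr::read_lines(path, progress = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
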