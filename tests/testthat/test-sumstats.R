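test_that("read_sumstats round-trips mapped fields and ignores extras", {
  x <- toy_sumstats()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  y <- read_sumstats(path)
  expect_equal(nrow(y), 5)
  expect_equal(y$beta, x$beta)
  expect_equal(y$effect_allele, x$effect_allele)

  # extra unmapped column is ignored with a message; mapped fields survive
  x2 <- dplyr::mutate(x, info_score = 0.99)
  write_sumstats(x2, path)
  expect_message(y2 <- read_sumstats(path), "ignoring unmapped")
  expect_equal(dplyr::select(y2, -dplyr::any_of("info_score")), y)

  # column remapping
  x3 <- dplyr::rename(x, rsid = snp, p = pval)
  readr::write_tsv(x3, path)
  y3 <- read_sumstats(path, column_map = c(snp = "rsid", pval = "p"))
  expect_equal(y3$snp, x$snp)
  expect_equal(y3$pval, x$pval)
})

test_that("invalid rows and missing columns are rejected with row context", {
  x <- toy_sumstats()
  path <- withr::local_tempfile(fileext = ".tsv")

  x_bad <- x; x_bad$se[3] <- 0
  write_sumstats(x_bad, path)
  expect_error(read_sumstats(path), "row 3")

  x_bad <- x; x_bad$beta[2] <- "oops"
  readr::write_tsv(x_bad, path)
  expect_error(read_sumstats(path), "unparsable numeric")

  readr::write_tsv(dplyr::select(x, -se), path)
  expect_error(read_sumstats(path), "mandatory")

  # alleles are upper-cased on read
  x_lc <- x; x_lc$effect_allele <- tolower(x_lc$effect_allele)
  readr::write_tsv(x_lc, path)
  expect_equal(read_sumstats(path)$effect_allele, x$effect_allele)
})

test_that("instrument selection thresholds and greedily prunes by LD", {
  x <- toy_sumstats()
  iv <- select_instruments(x, p_threshold = 5e-8)
  # rs5 fails the threshold; rs2 is distance-pruned by rs1 (200 kb on chr 1)
  expect_setequal(iv$snp, c("rs1", "rs3", "rs4"))

  # two SNPs in high LD: the smaller-p one wins
  two <- x[1:2, ]
  ld <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(two$snp, two$snp))
  kept <- select_instruments(two, 5e-8, ld = ld, r2_max = 0.001)
  expect_equal(kept$snp, "rs1")

  # no SNP passes
  expect_error(select_instruments(x, p_threshold = 1e-40), "empty instrument")
})

test_that("greedy LD pruning matches the exhaustive pairwise oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 10
    x <- tibble::tibble(
      snp = paste0("s", 1:n), chr = "1", pos = seq(1e6, by = 1e6, length.out = n),
      effect_allele = "A", other_allele = "G", eaf = runif(n, 0.1, 0.9),
      beta = rnorm(n), se = runif(n, 0.01, 0.02),
      pval = 10^-runif(n, 8, 20), n = 1e5)
    r <- matrix(runif(n * n), n)
    r2 <- (r + t(r)) / 2; diag(r2) <- 1
    dimnames(r2) <- list(x$snp, x$snp)
    kept <- select_instruments(x, 5e-8, ld = r2, r2_max = 0.3)$snp
    dropped <- setdiff(x$snp, kept)
    # every retained pair independent
    for (a in kept) for (b in setdiff(kept, a)) expect_lt(r2[a, b], 0.3)
    # every dropped SNP in LD with at least one retained SNP
    for (d in dropped) expect_true(any(r2[d, kept] >= 0.3))
  }
})

test_that("instrument selection is invariant to input row order", {
  x <- toy_sumstats()
  set.seed(9)
  perm <- x[sample.int(nrow(x)), ]
  expect_equal(select_instruments(x, 5e-8), select_instruments(perm, 5e-8))
})

test_that("distance-window pruning applies on the same chromosome only", {
  x <- toy_sumstats()
  # rs1 and rs2: same chr, 200 kb apart -> rs1 (smaller p) survives at 1 Mb
  kept <- select_instruments(x[1:2, ], 5e-8, window_bp = 1e6)
  expect_equal(kept$snp, "rs1")
  # rs3/rs4 are 4 Mb apart on chr 2: both survive
  kept2 <- select_instruments(x[3:4, ], 5e-8, window_bp = 1e6)
  expect_setequal(kept2$snp, c("rs3", "rs4"))
})

test_that("exclusion filters drop in precedence order and counts reconcile", {
  x <- toy_sumstats()
  # rs3 is palindromic A/T with eaf 0.50 -> ambiguous; rs5 palindromic C/G eaf 0.10 -> kept
  out <- apply_exclusions(x, blacklist = "rs1",
                          outcome_ids = c("rs2", "rs3", "rs5"),
                          eaf_ambiguity_band = c(0.42, 0.58))
  rep <- exclusion_report(out)
  expect_equal(rep$n_blacklisted, 1)          # rs1
  expect_equal(rep$n_missing_in_outcome, 1)   # rs4
  expect_equal(rep$n_palindromic_dropped, 1)  # rs3
  expect_equal(rep$n_retained, 2)             # rs2, rs5
  expect_setequal(out$snp, c("rs2", "rs5"))
  expect_equal(rep$n_input,
               rep$n_blacklisted + rep$n_missing_in_outcome +
                 rep$n_palindromic_dropped + rep$n_outlier_dropped + rep$n_retained)

  # a blacklisted palindromic SNP is counted once, under the blacklist
  out2 <- apply_exclusions(x, blacklist = "rs3", outcome_ids = x$snp)
  rep2 <- exclusion_report(out2)
  expect_equal(rep2$n_blacklisted, 1)
  expect_equal(rep2$n_palindromic_dropped, 0)

  # palindrome with missing eaf is dropped
  x_na <- x; x_na$eaf[3] <- NA
  rep3 <- exclusion_report(apply_exclusions(x_na, outcome_ids = x$snp))
  expect_equal(rep3$n_palindromic_dropped, 1)
})

test_that("random exclusion scenarios reconcile against a counting oracle", {
  set.seed(11)
  for (rep_i in 1:10) {
    n <- 30
    pal <- runif(n) < 0.3
    ea <- ifelse(pal, "A", "A"); oa <- ifelse(pal, "T", "G")
    x <- tibble::tibble(snp = paste0("v", 1:n), chr = "1", pos = 1:n * 1e5,
                        effect_allele = ea, other_allele = oa,
                        eaf = runif(n), beta = rnorm(n),
                        se = runif(n, 0.01, 0.1), pval = runif(n), n = 1e5)
    bl <- sample(x$snp, 5)
    oid <- sample(x$snp, 20)
    out <- apply_exclusions(x, bl, oid)
    r <- exclusion_report(out)
    expect_equal(r$n_input, 30)
    expect_equal(r$n_blacklisted + r$n_missing_in_outcome +
                   r$n_palindromic_dropped + r$n_retained, 30)
    expect_equal(nrow(out), r$n_retained)
    # oracle: direct set computation with the same precedence
    stay <- !(x$snp %in% bl)
    miss <- stay & !(x$snp %in% oid)
    amb <- stay & !miss & pal & x$eaf > 0.42 & x$eaf < 0.58
    expect_setequal(out$snp, x$snp[stay & !miss & !amb])
  }
})

test_that("harmonisation aligns, swaps, strand-flips and drops correctly", {
  expo <- tibble::tibble(snp = c("a", "b", "c", "d"), chr = "1", pos = 1:4 * 1e6,
                         effect_allele = c("A", "A", "A", "A"),
                         other_allele = c("G", "G", "G", "G"),
                         eaf = c(0.3, 0.3, 0.3, 0.3),
                         beta = c(0.1, 0.1, 0.1, 0.1), se = rep(0.01, 4),
                         pval = rep(1e-10, 4), n = 1e5)
  outc <- tibble::tibble(snp = c("a", "b", "c", "d"), chr = "1", pos = 1:4 * 1e6,
                         effect_allele = c("A", "G", "T", "A"),
                         other_allele = c("G", "A", "C", "C"),
                         eaf = c(0.3, 0.7, 0.7, 0.3),
                         beta = c(0.05, 0.05, 0.05, 0.05), se = rep(0.01, 4),
                         pval = rep(1e-4, 4), n = 1e5)
  h <- harmonize_pair(expo, outc)
  # a: same alleles -> copied; b: swapped -> negated;
  # c: T/C complements to A/G -> copied; d: A/C irreconcilable -> dropped
  expect_equal(h$snp, c("a", "b", "c"))
  expect_equal(h$by, c(0.05, -0.05, 0.05))
  expect_equal(attr(h, "dropped")$snp, "d")
})

test_that("palindromic SNPs are resolved by frequency concordance or dropped", {
  base <- tibble::tibble(snp = "p1", chr = "1", pos = 1e6,
                         effect_allele = "A", other_allele = "T",
                         beta = 0.1, se = 0.01, pval = 1e-10, n = 1e5)
  outc <- tibble::tibble(snp = "p1", chr = "1", pos = 1e6,
                         effect_allele = "A", other_allele = "T",
                         beta = 0.05, se = 0.01, pval = 1e-3, n = 1e5)
  # concordant frequencies (both minor) -> kept as-is
  h <- harmonize_pair(dplyr::mutate(base, eaf = 0.2),
                      dplyr::mutate(outc, eaf = 0.25))
  expect_equal(h$by, 0.05)
  # discordant frequencies -> effect flipped
  h2 <- harmonize_pair(dplyr::mutate(base, eaf = 0.2),
                       dplyr::mutate(outc, eaf = 0.75))
  expect_equal(h2$by, -0.05)
  # ambiguous frequency -> dropped (error because nothing is left)
  expect_error(harmonize_pair(dplyr::mutate(base, eaf = 0.5),
                              dplyr::mutate(outc, eaf = 0.5)),
               "dropped every shared SNP")
})

test_that("harmonisation is involutive on an already-aligned pair", {
  sim <- simulate_mediation_dag(sim_config(n_snp = 40, seed = 5,
                                           prop_mediator_snp = 0,
                                           selection_p = 1))
  h1 <- harmonize_pair(sim$exposure, sim$outcome)
  # reconstruct the outcome table from the harmonised set and re-harmonise
  outc2 <- tibble::tibble(snp = h1$snp, chr = "1", pos = seq_along(h1$snp),
                          effect_allele = h1$effect_allele,
                          other_allele = h1$other_allele, eaf = h1$eaf,
                          beta = h1$by, se = h1$sey, pval = 0.5, n = 1e5)
  expo2 <- sim$exposure[sim$exposure$snp %in% h1$snp, ]
  h2 <- harmonize_pair(expo2, outc2)
  expect_equal(h2$bx_1, h1$bx_1)
  expect_equal(h2$by, h1$by)
  expect_equal(nrow(attr(h2, "dropped")), 0)
})

test_that("allele relabelling of the exposure leaves causal estimates unchanged", {
  sim <- simulate_mediation_dag(sim_config(n_snp = 30, seed = 8,
                                           prop_mediator_snp = 0,
                                           selection_p = 1,
                                           palindrome_fraction = 0))
  expo <- sim$exposure
  flip <- dplyr::mutate(expo, beta = -beta,
                        eaf = 1 - eaf,
                        tmp = effect_allele, effect_allele = other_allele,
                        other_allele = tmp) |> dplyr::select(-tmp)
  h <- harmonize_pair(expo, sim$outcome)
  hf <- harmonize_pair(flip, sim$outcome)
  expect_equal(hf$bx_1, -h$bx_1)
  expect_equal(hf$by, -h$by)
  expect_equal(mr_ivw(hf, "fixed")$beta, mr_ivw(h, "fixed")$beta, tolerance = 1e-12)
})

test_that("multivariable harmonisation unions, dedups and drops missing SNPs", {
  sim <- simulate_mediation_dag(sim_config(n_snp = 60, seed = 3, selection_p = 1,
                                           palindrome_fraction = 0))
  iv_e <- dplyr::slice(sim$exposure, 1:5)
  iv_m <- dplyr::slice(sim$mediator, 4:8)   # overlaps iv_e on shared ids
  h <- harmonize_multi(sim$exposure, sim$mediator, sim$outcome, iv_e, iv_m)
  union_ids <- union(iv_e$snp, iv_m$snp)
  expect_equal(sort(h$snp), sort(union_ids))
  expect_equal(anyDuplicated(h$snp), 0)
  expect_equal(n_exposures(h), 2)

  # a SNP absent from the outcome study is dropped and recorded
  out2 <- sim$outcome[sim$outcome$snp != iv_e$snp[1], ]
  h2 <- harmonize_multi(sim$exposure, sim$mediator, out2, iv_e, iv_m)
  expect_false(iv_e$snp[1] %in% h2$snp)
  expect_true(iv_e$snp[1] %in% attr(h2, "dropped")$snp)
})

test_that("F statistics are squared z scores with an arithmetic mean", {
  h <- as_mr_harm(bx = c(0.1, 0, 0.05), sex = c(0.01, 0.01, 0.025),
                  by = rep(0, 3), sey = rep(0.01, 3))
  f <- f_statistics(h)
  expect_equal(f$per_snp$f, c(100, 0, 4))
  expect_equal(f$mean_f, mean(c(100, 0, 4)))
})
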