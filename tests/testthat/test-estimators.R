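test_that("Wald ratio handles the base, null and sign-flip cases", {
  e <- wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.1)
  expect_equal(e$ci_low, 0.5 - 1.96 * 0.1)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.01)$beta, 0)
  # flipping the SNP orientation flips bx and by together: same estimate
  expect_equal(wald_ratio(-0.1, 0.01, -0.05, 0.01)$beta, 0.5)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.01), "bx = 0")
})

test_that("IVW reproduces the weighted-least-squares closed form", {
  h <- as_mr_harm(bx = c(0.1, 0.2, 0.4), sex = rep(0.01, 3),
                  by = c(0.02, 0.05, 0.09), sey = c(0.01, 0.01, 0.02))
  e <- mr_ivw(h, "fixed")
  expect_equal(e$beta, 7 / 30, tolerance = 1e-12)
  expect_equal(e$se, 1 / 30, tolerance = 1e-12)

  # single SNP reduces exactly to the Wald ratio
  h1 <- as_mr_harm(0.1, 0.01, 0.05, 0.02)
  e1 <- mr_ivw(h1, "fixed")
  w1 <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(e1$beta, w1$beta)
  expect_equal(e1$se, w1$se)

  # matches the generic WLS oracle on random sets
  for (s in 1:5) {
    h <- random_harm(50, seed = s, sey = 0.05)
    o <- wls_oracle(matrix(h$bx_1), h$by, 1 / h$sey^2)
    e <- mr_ivw(h, "fixed")
    expect_equal(e$beta, unname(o$beta), tolerance = 1e-10)
    expect_equal(e$se, unname(o$se_fixed), tolerance = 1e-10)
  }
})

test_that("random-effects IVW never reports a smaller SE than fixed", {
  for (s in 1:20) {
    h <- random_harm(10, seed = 100 + s, sey = 0.03)
    ef <- mr_ivw(h, "fixed"); er <- mr_ivw(h, "random")
    expect_equal(ef$beta, er$beta)
    expect_gte(er$se, ef$se)
    if (ef$heterogeneity$Q <= ef$heterogeneity$df) expect_equal(er$se, ef$se)
  }
})

test_that("Cochran's Q matches hand computation and is permutation-invariant", {
  h <- as_mr_harm(bx = c(0.1, 0.2, 0.4), sex = rep(0.01, 3),
                  by = c(0.02, 0.05, 0.09), sey = c(0.01, 0.01, 0.02))
  q <- cochran_q(h, mr_ivw(h, "fixed")$beta)
  expect_equal(q$Q, 0.25, tolerance = 1e-12)
  expect_equal(q$df, 2)
  expect_equal(q$i2, max(0, (0.25 - 2) / 0.25))

  # identical ratios: Q = 0, I2 = 0
  h0 <- as_mr_harm(bx = c(0.1, 0.2), sex = rep(0.01, 2),
                   by = c(0.05, 0.10), sey = rep(0.01, 2))
  q0 <- cochran_q(h0, 0.5)
  expect_equal(q0$Q, 0)
  expect_equal(q0$i2, 0)

  perm <- h[c(3, 1, 2), ]
  attr(perm, "exposure_names") <- attr(h, "exposure_names")
  expect_equal(cochran_q(perm, 7 / 30)$Q, q$Q)
})

test_that("Egger recovers exact lines and matches the WLS oracle", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- as_mr_harm(bx, rep(0.01, 4), 0.01 + 0.5 * bx, rep(0.05, 4))
  eg <- mr_egger(h)
  expect_equal(eg$estimate$beta, 0.5, tolerance = 1e-10)
  expect_equal(eg$pleiotropy$intercept, 0.01, tolerance = 1e-10)

  # proportional data -> zero intercept
  h2 <- as_mr_harm(bx, rep(0.01, 4), 0.4 * bx, rep(0.05, 4))
  expect_equal(mr_egger(h2)$pleiotropy$intercept, 0, tolerance = 1e-10)

  # random data against the closed-form weighted regression with intercept
  for (s in 1:5) {
    h3 <- random_harm(30, seed = 200 + s, sey = 0.03, intercept = 0.005)
    o <- wls_oracle(cbind(1, h3$bx_1), h3$by, 1 / h3$sey^2)
    eg3 <- mr_egger(h3)
    expect_equal(eg3$estimate$beta, unname(o$beta[2]), tolerance = 1e-10)
    expect_equal(eg3$pleiotropy$intercept, unname(o$beta[1]), tolerance = 1e-10)
    expect_equal(eg3$estimate$se, unname(o$se_overdispersed[2]), tolerance = 1e-8)
  }
  expect_error(mr_egger(h[1:2, ]), "at least 3")
})

test_that("weighted median interpolates the weighted 50th percentile", {
  # symmetric equal weights
  h <- as_mr_harm(bx = rep(1, 3), sex = rep(0.01, 3),
                  by = c(0.4, 0.5, 0.6), sey = rep(1, 3))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 0.5)

  # ratios {0.1,0.2,0.3,0.9} with weights {1,1,1,3} -> 0.45
  h2 <- as_mr_harm(bx = c(1, 1, 1, sqrt(3)), sex = rep(0.01, 4),
                   by = c(0.1, 0.2, 0.3, 0.9 * sqrt(3)), sey = rep(1, 4))
  expect_equal(mr_weighted_median(h2, n_boot = 50, seed = 1)$beta, 0.45,
               tolerance = 1e-12)

  # penalisation downweights the heterogeneous SNP and moves the estimate
  # toward the consensus of the valid majority
  set.seed(4)
  n <- 21
  bx <- rnorm(n, 0.2, 0.02); sey <- rep(0.01, n)
  by <- 0.3 * bx + rnorm(n, 0, sey)
  by[1:4] <- by[1:4] + 0.15      # strongly pleiotropic minority
  hp <- as_mr_harm(bx, rep(1e-4, n), by, sey)
  plain <- mr_weighted_median(hp, n_boot = 50, seed = 2)$beta
  pen <- mr_weighted_median(hp, penalized = TRUE, n_boot = 50, seed = 2)$beta
  expect_lt(abs(pen - 0.3), abs(plain - 0.3) + 1e-9)
  expect_error(mr_weighted_median(hp[1:2, ]), "at least 3")
})

test_that("weighted median is consistent with <=50% invalid weight", {
  set.seed(5)
  hits <- replicate(20, {
    n <- 40
    bx <- rnorm(n, 0.2, 0.03)
    sey <- rep(0.01, n)
    by <- 0.25 * bx + rnorm(n, 0, sey)
    bad <- 1:12                       # 30% of SNPs, similar weight share
    by[bad] <- by[bad] + 0.1
    h <- as_mr_harm(bx, rep(0.005, n), by, sey)
    e <- mr_weighted_median(h, n_boot = 100)
    abs(e$beta - 0.25) < 3 * e$se
  })
  expect_gte(mean(hits), 0.9)
})

test_that("maximum likelihood reduces to Wald and IVW in their limits", {
  h1 <- as_mr_harm(0.1, 0.01, 0.05, 0.02)
  expect_equal(mr_max_likelihood(h1)$beta, 0.5, tolerance = 1e-6)

  h <- as_mr_harm(c(0.1, 0.2, 0.3), rep(1e-8, 3),
                  c(0.021, 0.040, 0.062), rep(0.01, 3))
  expect_equal(mr_max_likelihood(h)$beta, mr_ivw(h, "fixed")$beta,
               tolerance = 1e-4)
  expect_equal(mr_max_likelihood(h)$se, mr_ivw(h, "fixed")$se,
               tolerance = 1e-4)

  # permutation invariance
  hp <- random_harm(15, seed = 7, sey = 0.02)
  hq <- hp[sample(15), ]
  attr(hq, "exposure_names") <- attr(hp, "exposure_names")
  expect_equal(mr_max_likelihood(hp)$beta, mr_max_likelihood(hq)$beta,
               tolerance = 1e-8)
})

test_that("radial IVW matches first-order IVW when exposure SEs vanish", {
  h <- as_mr_harm(c(0.1, 0.2, 0.3), rep(1e-10, 3),
                  c(0.02, 0.05, 0.05), rep(0.01, 3))
  expect_equal(mr_radial_ivw(h)$beta, mr_ivw(h, "fixed")$beta, tolerance = 1e-6)

  h1 <- as_mr_harm(0.1, 0.01, 0.05, 0.02)
  expect_equal(mr_radial_ivw(h1)$beta, wald_ratio(0.1, 0.01, 0.05, 0.02)$beta)

  # modified weights strictly decrease in sex, all else equal
  w_of <- function(sex) 1 / (0.01^2 / 0.2^2 + 0.06^2 * sex^2 / 0.2^4)
  sexes <- c(0.001, 0.005, 0.01, 0.02)
  expect_true(all(diff(w_of(sexes)) < 0))
})

test_that("every estimator is sign-equivariant in the outcome", {
  h <- random_harm(12, seed = 31, sey = 0.03)
  hneg <- h; hneg$by <- -h$by
  for (fit in list(function(x) mr_ivw(x, "fixed"),
                   function(x) mr_ivw(x, "random"),
                   function(x) mr_egger(x)$estimate,
                   mr_max_likelihood,
                   mr_radial_ivw)) {
    a <- fit(h); b <- fit(hneg)
    expect_equal(b$beta, -a$beta, tolerance = 1e-6)
    expect_equal(b$se, a$se, tolerance = 1e-6)
  }
  # the weighted-median point estimate mirrors exactly; its SE is a
  # bootstrap quantity, equal in distribution only
  wa <- mr_weighted_median(h, n_boot = 100, seed = 3)
  wb <- mr_weighted_median(hneg, n_boot = 100, seed = 3)
  expect_equal(wb$beta, -wa$beta, tolerance = 1e-12)
  expect_equal(wb$se, wa$se, tolerance = 0.3)
})

test_that("leave-one-out returns one estimate per SNP and detects outliers", {
  # identical SNPs: every omission gives the full estimate
  h0 <- as_mr_harm(rep(0.2, 5), rep(0.01, 5), rep(0.06, 5), rep(0.01, 5))
  loo0 <- mr_leave_one_out(h0)
  expect_equal(nrow(loo0$loo), 5)
  expect_equal(loo0$max_abs_deviation, 0, tolerance = 1e-12)

  # a planted outlier: omitting it moves the estimate toward truth
  set.seed(13)
  n <- 15
  bx <- rnorm(n, 0.2, 0.02); sey <- rep(0.01, n)
  by <- 0.3 * bx + rnorm(n, 0, sey)
  by[n] <- by[n] + 0.2
  h <- as_mr_harm(bx, rep(0.005, n), by, sey)
  loo <- mr_leave_one_out(h)
  omit_out <- loo$loo$beta[loo$loo$omitted == h$snp[n]]
  full <- loo$full$beta
  expect_lt(abs(omit_out - 0.3), abs(full - 0.3))
})

test_that("binary-outcome power is alpha at the null and monotone", {
  expect_equal(power_binary(2e5, 0.3, 0.02, or_alt = 1), 0.05)
  expect_gt(power_binary(1e8, 0.3, 0.02, 1.1), 0.999)
  ns <- c(1e4, 5e4, 2e5, 1e6)
  expect_true(all(diff(sapply(ns, power_binary, case_fraction = 0.3,
                              r2_gx = 0.02, or_alt = 1.2)) > 0))
  r2s <- c(0.005, 0.01, 0.02, 0.05)
  expect_true(all(diff(sapply(r2s, function(r)
    power_binary(2e5, 0.3, r, 1.2))) > 0))
  ors <- c(1.05, 1.1, 1.2, 1.4)
  expect_true(all(diff(sapply(ors, function(o)
    power_binary(2e5, 0.3, 0.02, o))) > 0))
  # protective effects of the same magnitude give identical power
  expect_equal(power_binary(2e5, 0.3, 0.02, 1.25),
               power_binary(2e5, 0.3, 0.02, 0.8))
})
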