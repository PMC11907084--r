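# Independent oracles used across tests. These are deliberately written
# from first principles (solve() on the normal equations, explicit step-up
# minima) so they share no code with the package implementation.

# Closed-form weighted least squares: returns coefficients and the
# covariance-based SEs, both the naive (sigma-free, "fixed") form and with
# multiplicative overdispersion floored at 1.
wls_oracle <- function(X, y, w) {
  X <- as.matrix(X)
  XtWX <- t(X) %*% (w * X)
  XtWy <- t(X) %*% (w * y)
  beta <- solve(XtWX, XtWy)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(w * res^2) / df
  se_fixed <- sqrt(diag(solve(XtWX)))
  list(beta = drop(beta), se_fixed = se_fixed,
       se_overdispersed = se_fixed * max(1, sqrt(sigma2)),
       sigma2 = sigma2)
}

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Random single-exposure harmonised set with controllable noise scales.
random_harm <- function(n, seed = 1, sex = 0.01, sey = 0.02, slope = 0.3,
                        intercept = 0) {
  set.seed(seed)
  bx <- abs(rnorm(n, 0.15, 0.05))   # oriented to the exposure-increasing allele
  by <- intercept + slope * bx + rnorm(n, 0, sey)
  as_mr_harm(bx = bx, sex = rep(sex, n), by = by,
             sey = runif(n, 0.5, 1.5) * sey)
}

# Small well-formed sumstats table used by the I/O and filtering tests.
toy_sumstats <- function() {
  tibble::tibble(
    snp = paste0("rs", 1:5),
    chr = c("1", "1", "2", "2", "3"),
    pos = c(1e6, 1.2e6, 5e6, 9e6, 2e6),
    effect_allele = c("A", "C", "A", "G", "C"),
    other_allele = c("G", "T", "T", "A", "G"),
    eaf = c(0.3, 0.2, 0.5, 0.4, 0.1),
    beta = c(0.10, -0.08, 0.05, 0.12, -0.02),
    se = c(0.01, 0.012, 0.009, 0.02, 0.015),
    pval = c(1e-23, 3e-11, 2.7e-8, 1e-9, 0.18),
    n = rep(250000, 5)
  )
}
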