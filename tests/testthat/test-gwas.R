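# Association scan machinery: filtering, median regression, bootstrap
# inference, diagnostics, scan bookkeeping.

sim_design <- function(n = 80, p = 3, seed = 1) {
  set.seed(seed)
  X <- cbind(intercept = 1, carrier = rbinom(n, 1, 0.2),
             age = rnorm(n, 40, 10))[, seq_len(p), drop = FALSE]
  X
}

test_that("prevalence filter applies strict bounds on carrier proportion", {
  set.seed(2)
  n <- 100
  counts <- c(1, 2, 50, 99, 0, 100)
  G <- sapply(counts, function(k) sample(rep(c(1L, 0L), c(k, n - k))))
  colnames(G) <- paste0("v", seq_along(counts))
  rownames(G) <- paste0("s", 1:n)
  kept <- prevalence_filter(G, 0.01, 0.99)
  expect_setequal(colnames(kept), c("v2", "v3"))  # counts 2 and 50
  expect_identical(attr(kept, "n_dropped"), 4L)
  expect_error(prevalence_filter(G[, 0, drop = FALSE]), "empty")
})

test_that("LAD fit is exact on noiseless data and medians", {
  X <- sim_design(n = 60, p = 3)
  beta_true <- c(100, -40, 2)
  y <- as.numeric(X %*% beta_true)
  f <- lad_fit(y, X)
  expect_equal(unname(f$coefficients), beta_true, tolerance = 1e-10)
  expect_equal(f$objective, 0, tolerance = 1e-8)
  # intercept-only model returns a median of y
  y2 <- c(1, 2, 3, 9, 50)
  f2 <- lad_fit(y2, matrix(1, 5, 1, dimnames = list(NULL, "i")))
  expect_equal(sum(abs(y2 - f2$coefficients)),
               sum(abs(y2 - median(y2))))
  # rank deficiency is reported with the offending column
  Xbad <- cbind(X, carrier2 = X[, "carrier"])
  expect_error(lad_fit(y, Xbad), "carrier2")
  expect_error(lad_fit(y[1:2], X[1:2, ]), "more observations")
})

test_that("LAD objective never exceeds the OLS objective in L1", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(30:100, 1)
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    colnames(X) <- c("i", "a", "b")
    y <- as.numeric(X %*% c(5, 1, -2)) +
      if (s %% 2) rnorm(n, 0, 3) else rcauchy(n)
    f <- lad_fit(y, X)
    ols <- stats::lm.fit(X, y)
    expect_lte(f$objective, sum(abs(ols$residuals)) + 1e-9)
  }
})

test_that("bootstrap inference follows the normal-approximation rules", {
  X <- sim_design(n = 120, p = 3, seed = 4)
  y <- as.numeric(X %*% c(300, -50, 1)) + rnorm(120, 0, 60)
  inf <- bootstrap_inference(y, X, B = 200, seed = 9, term = "carrier")
  expect_equal(inf$ci_lower, inf$beta - 1.96 * inf$se)
  expect_equal(inf$ci_upper, inf$beta + 1.96 * inf$se)
  expect_equal(inf$t, inf$beta / inf$se)
  expect_equal(inf$p, 2 * pnorm(-abs(inf$t)))
  # reproducible given the seed
  inf2 <- bootstrap_inference(y, X, B = 200, seed = 9, term = "carrier")
  expect_identical(inf$se, inf2$se)
  # degenerate: noiseless outcome leaves zero bootstrap spread
  y0 <- as.numeric(X %*% c(10, 5, 0.1))
  inf0 <- bootstrap_inference(y0, X, B = 50, seed = 2, term = "carrier")
  expect_true(inf0$degenerate)
  expect_true(is.na(inf0$p))
})

test_that("residual diagnostics flag heavy-tailed and heteroscedastic data", {
  set.seed(31)
  # clean OLS world: flags should mostly pass (each test has ~5% size)
  ok <- 0L
  n_sim <- 120
  for (i in seq_len(n_sim)) {
    X <- cbind(1, rnorm(200), rbinom(200, 1, 0.3))
    y <- as.numeric(X %*% c(1, 2, 1)) + rnorm(200)
    if (residual_diagnostics(y, X)$ols_ok) ok <- ok + 1L
  }
  # expected pass rate ~0.95^2 = 0.90; allow 2.5 binomial SEs below
  expect_gte(ok / n_sim, 0.9025 - 2.5 * sqrt(0.9 * 0.1 / n_sim))
  # Laplace noise violates normality almost surely at n = 724
  bad <- 0L
  for (i in 1:30) {
    X <- cbind(1, rnorm(724))
    y <- as.numeric(X %*% c(1, 2)) +
      mitocohort:::rlaplace(724, 50)
    if (!residual_diagnostics(y, X)$ols_ok) bad <- bad + 1L
  }
  expect_gte(bad / 30, 0.9)
  # heteroscedasticity is caught by the Breusch-Pagan component
  het <- 0L
  for (i in 1:30) {
    x1 <- runif(500, 1, 10)
    X <- cbind(1, x1)
    y <- 2 + x1 + rnorm(500, 0, x1)
    d <- residual_diagnostics(y, X)
    if (!is.na(d$bp_p) && d$bp_p < 0.05) het <- het + 1L
  }
  expect_gte(het / 30, 0.9)
  # constant outcome: error-free degenerate report
  expect_true(residual_diagnostics(rep(5, 50), cbind(1, rnorm(50)))$ols_ok)
})

test_that("scan bookkeeping derives tests and threshold from kept columns", {
  ref <- test_ref()
  cfg <- sim_config(n_participants = 150L, n_substitutions = 25L,
                    n_indels = 0L, seed = 41L)
  sim <- simulate_cohort(cfg, ref)
  G <- genotype_matrix(sim)
  scan <- suppressWarnings(
    run_scan(G, sim$metadata, outcomes = c("cd4_pre", "cd4_post"),
             B = 25L, seed = 5L, ref = ref))
  expect_identical(scan$n_tests, scan$n_kept * 2L)
  expect_equal(scan$threshold, 0.05 / scan$n_tests)
  expect_identical(nrow(scan$results), scan$n_tests)
  # single substitution, single outcome: threshold is alpha itself
  one <- prevalence_filter(G)[, 1, drop = FALSE]
  scan1 <- suppressWarnings(
    run_scan(one, sim$metadata, outcomes = "cd4_pre", B = 10L, seed = 5L))
  expect_equal(scan1$threshold, 0.05)
})

test_that("scan results are invariant to column order", {
  ref <- test_ref()
  cfg <- sim_config(n_participants = 120L, n_substitutions = 10L,
                    n_indels = 0L, seed = 43L)
  sim <- simulate_cohort(cfg, ref)
  G <- genotype_matrix(sim)
  s1 <- suppressWarnings(
    run_scan(G, sim$metadata, outcomes = "cd4_pre", B = 40L, seed = 7L))
  s2 <- suppressWarnings(
    run_scan(G[, rev(seq_len(ncol(G)))], sim$metadata,
             outcomes = "cd4_pre", B = 40L, seed = 7L))
  r1 <- s1$results[order(s1$results$substitution), ]
  r2 <- s2$results[order(s2$results$substitution), ]
  expect_equal(r1$beta, r2$beta)
  expect_equal(r1$se, r2$se)
  expect_equal(r1$p, r2$p)
  # participant order leaves the point estimates unchanged
  perm <- sample(nrow(G))
  s3 <- suppressWarnings(
    run_scan(G[perm, ], sim$metadata[perm, ], outcomes = "cd4_pre",
             B = 10L, seed = 7L))
  r3 <- s3$results[order(s3$results$substitution), ]
  expect_equal(r1$beta, r3$beta)
})

test_that("a planted effect is the scan's top hit", {
  ref <- test_ref()
  hits <- 0L
  n_runs <- 5L
  for (r in seq_len(n_runs)) {
    panel <- sim_variant_panel(ref, 20L, 0L, freq_range = c(0.05, 0.4),
                               seed = 300L + r)
    panel$frequency[1] <- 0.10
    panel$effect[1] <- -55
    cfg <- sim_config(n_participants = 724L, variants = panel,
                      seed = 500L + r)
    sim <- simulate_cohort(cfg, ref)
    scan <- run_scan(genotype_matrix(sim), sim$metadata,
                     outcomes = "cd4_post", B = 100L, seed = r)
    if (scan$results$substitution[1] == panel$m_notation[1]) hits <- hits + 1L
  }
  expect_gte(hits, n_runs - 1L)
})
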