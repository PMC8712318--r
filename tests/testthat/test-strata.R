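# Stratification and subpopulation statistics.

test_that("the stratum key space has exactly 16 cells", {
  ref <- test_ref()
  fx <- make_fixture_suite(ref)
  st <- stratify(fx$strata_cohort)
  expect_identical(nrow(st$table), 16L)
  expect_identical(unique(st$table$n), 5L)
  expect_false(any(st$table$below_min))
  # partition: stratum sizes sum to the filtered cohort size
  expect_identical(sum(st$table$n), st$n_total)
})

test_that("boundary participants land in the right stratum", {
  meta <- data.frame(id = "b1", gender = "female", age = 29,
                     ethnicity = "Han", transmission = "heterosexual",
                     cd4_pre = 199, stringsAsFactors = FALSE)
  st <- stratify(meta, min_size = 1L)
  hit <- st$table[st$table$n == 1L, ]
  expect_identical(hit$gender, "female")
  expect_identical(hit$age_group, "17-29")
  expect_identical(hit$immune_level, "severe")
  # 200 cells/ul is mild; age 30 is the second group
  meta2 <- data.frame(id = "b2", gender = "male", age = 30,
                      ethnicity = "Han", transmission = "heterosexual",
                      cd4_pre = 200, stringsAsFactors = FALSE)
  st2 <- stratify(meta2, min_size = 1L)
  hit2 <- st2$table[st2$table$n == 1L, ]
  expect_identical(hit2$age_group, "30-44")
  expect_identical(hit2$immune_level, "mild")
  expect_error(stratify(meta[0, ]), "empty")
})

test_that("ethnicity filtering excludes non-matching participants", {
  ref <- test_ref()
  meta <- make_fixture_suite(ref)$strata_cohort
  meta$ethnicity[1:7] <- "minority"
  st <- stratify(meta, ethnicity = "Han")
  expect_identical(st$n_total, nrow(meta) - 7L)
  st_all <- stratify(meta, ethnicity = NULL)
  expect_identical(st_all$n_total, nrow(meta))
})

test_that("simulated cohorts stratify to their ground-truth counts", {
  ref <- test_ref()
  sim <- simulate_cohort(sim_config(n_participants = 400L, seed = 11L), ref)
  st <- stratify(sim$metadata, ethnicity = "Han")
  truth <- sim$metadata[sim$metadata$ethnicity == "Han", ]
  key <- paste(truth$gender, truth$age_group, truth$immune_level, sep = "|")
  for (k in seq_len(nrow(st$table))) {
    kk <- paste(st$table$gender[k], st$table$age_group[k],
                st$table$immune_level[k], sep = "|")
    expect_identical(st$table$n[k], sum(key == kk))
  }
})

test_that("age trends recover known slopes", {
  expect_equal(age_trend(c(1, 2, 3, 4))$beta, 1)
  expect_equal(age_trend(c(7, 7, 7, 7))$beta, 0)
  vals <- c(0.3, 0.9, 1.1, 2.2)
  tr <- age_trend(vals, codes = 1:4)
  xv <- 1:4
  expect_equal(tr$beta,
               sum((xv - mean(xv)) * (vals - mean(vals))) /
                 sum((xv - mean(xv))^2))
  # slope sign flips when the age-group order is reversed
  expect_equal(age_trend(rev(vals), codes = 1:4)$beta, -tr$beta)
  expect_error(age_trend(c(1, NA, NA, 2)), ">= 3")
})

test_that("rank-sum comparison matches an exhaustive permutation oracle", {
  a <- c(1.2, 3.4, 5.1)
  b <- c(2.2, 4.8, 6.9)
  got <- compare_bias_density(a, b)
  # exact two-sided p by enumerating all choose(6,3) group assignments
  pooled <- c(a, b)
  W_obs <- sum(rank(pooled)[1:3]) - 3 * 4 / 2
  combs <- utils::combn(6, 3)
  Ws <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]) - 6)
  # two-sided: distance from the mean of the null distribution
  dev <- abs(Ws - mean(Ws))
  p_exact <- mean(dev >= abs(W_obs - mean(Ws)) - 1e-12)
  expect_equal(got$p, p_exact)
  expect_equal(got$statistic, W_obs)
  # identical groups give p = 1
  expect_equal(compare_bias_density(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # complete separation at n = 10 pushes W to its extreme
  sep <- compare_bias_density(1:10, 101:110)
  expect_equal(sep$statistic, 0)
  expect_lt(sep$p, 0.001)
  expect_error(compare_bias_density(numeric(0), 1:3), "nonempty")
})

test_that("platform comparison implements the Welch t-test", {
  ident <- platform_comparison(c(4, 5, 6), c(4, 5, 6))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2)
  got <- platform_comparison(a, b)
  se <- sqrt(var(a) / 10 + var(b) / 10)
  t_manual <- (mean(a) - mean(b)) / se
  df_manual <- se^4 / ((var(a) / 10)^2 / 9 + (var(b) / 10)^2 / 9)
  expect_equal(got$t, t_manual)
  expect_equal(got$df, df_manual)
  expect_equal(got$p, 2 * pt(-abs(t_manual), df_manual))
  expect_error(platform_comparison(1, c(1, 2)), "size >= 2")
})

test_that("the Welch test holds its nominal size under the null", {
  set.seed(5)
  rej <- 0L
  for (i in 1:1000) {
    a <- rnorm(15, 10, 3)
    b <- rnorm(25, 10, 3)
    if (platform_comparison(a, b)$p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 1000, 0.03)
  expect_lt(rej / 1000, 0.075)
})

test_that("per-stratum metrics reuse the cohort metric machinery", {
  ref <- test_ref()
  cfg <- sim_config(n_participants = 250L, n_substitutions = 30L,
                    n_indels = 0L, seed = 21L)
  sim <- simulate_cohort(cfg, ref, sequences = FALSE)
  # build calls directly from the ground-truth ledger
  carr <- sim$carriers
  long <- which(carr == 1L, arr.ind = TRUE)
  panel <- sim$variant_panel
  df <- data.frame(sample_id = rownames(carr)[long[, 1]],
                   position = panel$position[long[, 2]],
                   ref = panel$ref[long[, 2]],
                   alt = panel$alt[long[, 2]],
                   kind = panel$kind[long[, 2]],
                   stringsAsFactors = FALSE)
  x <- toy_calls(df, ref, samples = rownames(carr))
  res <- stratum_age_trends(x, sim$metadata, ref, min_size = 0L)
  expect_s3_class(res$strata, "mito_strata")
  # stratum metric values equal a direct subset computation
  st <- res$strata
  k <- which(st$table$n > 0)[1]
  ids <- intersect(st$members[[k]], x$samples)
  direct <- diversity_density_table(x, ref, "macrodivision", samples = ids)
  sub <- res$metrics[res$metrics$gender == st$table$gender[k] &
                       res$metrics$age_group == st$table$age_group[k] &
                       res$metrics$immune_level == st$table$immune_level[k], ]
  expect_equal(sort(sub$diversity_density),
               sort(direct$diversity_density))
})
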