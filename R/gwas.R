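# Genome-wide association scan of mtDNA substitutions against CD4+
# T-cell outcomes: prevalence filtering, least-absolute-deviation
# (median) regression, case-resampling bootstrap inference and
# Bonferroni correction.

#' Build a binary genotype (carrier) matrix
#'
#' Rows are participants, columns are distinct definite substitution
#' types (indels and ambiguous calls are excluded from association
#' analyses); entries are 0/1 carrier status.
#'
#' @param x A `mito_calls` object, or a `mito_cohort_sim` from
#'   [simulate_cohort()] (which uses the ground-truth ledger).
#' @param ... Unused.
#' @return Integer matrix with participant row names and m-notation
#'   column names.
#' @export
genotype_matrix <- function(x, ...) UseMethod("genotype_matrix")

#' @export
genotype_matrix.mito_calls <- function(x, ...) {
  reg <- x$registry
  keep <- reg$m_notation[reg$kind == "substitution" & reg$definite]
  calls <- x$calls[x$calls$m_notation %in% keep, , drop = FALSE]
  G <- matrix(0L, length(x$samples), length(keep),
              dimnames = list(x$samples, keep))
  if (nrow(calls) > 0L) {
    G[cbind(match(calls$sample_id, x$samples),
            match(calls$m_notation, keep))] <- 1L
  }
  G
}

#' Filter substitutions by carrier prevalence
#'
#' Keeps columns whose carrier proportion `c/n` lies strictly between
#' `low` and `high`. With n = 724 and the default bounds (1%, 99%) the
#' smallest kept carrier count is 8 and the largest is 716.
#'
#' @param matrix Binary genotype matrix (participants x substitutions).
#' @param low,high Strict prevalence bounds (defaults 0.01 and 0.99).
#' @return The filtered matrix, with attributes `n_kept`, `n_dropped`
#'   and `kept_range` (the min/max kept carrier counts).
#' @export
prevalence_filter <- function(matrix, low = 0.01, high = 0.99) {
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) stop("empty genotype matrix")
  n <- nrow(matrix)
  counts <- colSums(matrix)
  keep <- counts / n > low & counts / n < high
  out <- matrix[, keep, drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "kept_range") <- if (any(keep)) range(counts[keep]) else
    c(NA_integer_, NA_integer_)
  out
}

#' Least absolute deviation (median) regression
#'
#' Fits coefficients minimizing the sum of absolute residuals (quantile
#' regression at tau = 0.5) by an exact basis-exchange descent: the
#' solution interpolates p observations and satisfies the subgradient
#' optimality condition, so the attained objective equals the linear
#' programming optimum. Deterministic under the fixed tie-break rule.
#'
#' @param y Outcome vector.
#' @param X Design matrix (n > ncol(X), full column rank).
#' @return List with `coefficients` (named as X's columns), `objective`
#'   (the minimised sum of absolute residuals), `fitted`, `residuals`
#'   and `iterations`.
#' @export
lad_fit <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) <= ncol(X)) stop("need more observations than parameters")
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- lad_solve_cpp(X, y)
  if (!isTRUE(res$ok)) stop("LAD solver failed to build a basis")
  beta <- as.numeric(res$coefficients)
  names(beta) <- colnames(X)
  fitted <- as.numeric(X %*% beta)
  list(coefficients = beta, objective = res$objective, fitted = fitted,
       residuals = y - fitted, iterations = res$iterations,
       basis = res$basis)
}

#' Bootstrap inference for one median-regression coefficient
#'
#' Case-resampling bootstrap: rows of (y, X) are resampled jointly B
#' times and the LAD fit is repeated; the bootstrap standard error is
#' the standard deviation of the replicate coefficient estimates. The
#' confidence interval, t and p use the normal approximation
#' (CI = beta +/- 1.96 SE, t = beta/SE, p = 2(1 - Phi(|t|))), which is
#' the rule under which published coefficient tables are internally
#' consistent. A percentile CI is also returned.
#'
#' @param y,X Outcome and design matrix (see [lad_fit()]).
#' @param B Number of bootstrap replications (default 1000).
#' @param seed Seed for the private bootstrap RNG stream.
#' @param term Coefficient of interest (index or column name;
#'   default 2, the column after the intercept).
#' @return List with `beta`, `se`, `ci_lower`, `ci_upper`, `t`, `p`,
#'   `ci_percentile`, `n_dropped` (singular replicates), `B` and
#'   `degenerate` (TRUE when the bootstrap SE is zero, in which case
#'   `t` and `p` are NA).
#' @export
bootstrap_inference <- function(y, X, B = 1000L, seed = 1L, term = 2L) {
  fit <- lad_fit(y, X)
  X <- as.matrix(X)
  if (is.character(term)) term <- match(term, colnames(X))
  beta <- unname(fit$coefficients[term])
  bo <- lad_boot_cpp(X, as.numeric(y), fit$coefficients, fit$basis,
                     as.integer(B),
                     as.integer(seed) %% .Machine$integer.max)
  reps <- bo$coefficients[, term]
  reps <- reps[is.finite(reps)]
  if (bo$dropped > 0.1 * B) {
    warning(bo$dropped, " of ", B, " bootstrap replicates dropped as singular")
  }
  se <- stats::sd(reps)
  if (!is.finite(se) || se <= 1e-10 * max(1, abs(beta))) {
    return(list(beta = beta, se = se, ci_lower = beta, ci_upper = beta,
                t = NA_real_, p = NA_real_,
                ci_percentile = c(beta, beta),
                n_dropped = bo$dropped, B = B, degenerate = TRUE))
  }
  tstat <- beta / se
  list(
    beta = beta, se = se,
    ci_lower = beta - 1.96 * se, ci_upper = beta + 1.96 * se,
    t = tstat, p = 2 * stats::pnorm(-abs(tstat)),
    ci_percentile = unname(stats::quantile(reps, c(0.025, 0.975))),
    n_dropped = bo$dropped, B = B, degenerate = FALSE
  )
}

#' Residual diagnostics gating the model family
#'
#' Fits ordinary least squares and tests the residuals for
#' homoscedasticity (Breusch-Pagan) and normality (Shapiro-Wilk,
#' subsampled above 5,000 observations). The flags only report whether
#' OLS assumptions hold; the association scan itself always uses median
#' regression.
#'
#' @param y,X Outcome and design matrix.
#' @param alpha Significance level for both tests (default 0.05).
#' @return List with `ols_ok`, `bp_stat`, `bp_p`, `shapiro_stat`,
#'   `shapiro_p`.
#' @export
residual_diagnostics <- function(y, X, alpha = 0.05) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  fit <- stats::lm.fit(X, y)
  r <- fit$residuals
  if (stats::var(y) == 0 || stats::var(r) == 0) {
    return(list(ols_ok = TRUE, bp_stat = NA_real_, bp_p = NA_real_,
                shapiro_stat = NA_real_, shapiro_p = NA_real_,
                degenerate = TRUE))
  }
  # Breusch-Pagan (Koenker's studentized form): n R^2 of r^2 on X
  aux <- stats::lm.fit(X, r^2)
  r2aux <- 1 - sum(aux$residuals^2) / sum((r^2 - mean(r^2))^2)
  df <- fit$rank - 1L
  bp <- length(y) * r2aux
  bp_p <- if (df >= 1L) stats::pchisq(bp, df, lower.tail = FALSE) else
    NA_real_
  rs <- if (length(r) > 5000L) {
    r[round(seq(1L, length(r), length.out = 5000L))]
  } else r
  sw <- stats::shapiro.test(rs)
  list(
    ols_ok = (is.na(bp_p) || bp_p > alpha) && sw$p.value > alpha,
    bp_stat = bp, bp_p = bp_p,
    shapiro_stat = unname(sw$statistic), shapiro_p = sw$p.value,
    degenerate = FALSE
  )
}

# Reference-level dummy design for the covariates of each outcome model.
# pre-treatment model: gender, age, ethnicity, transmission.
# post-treatment model: + pre CD4, regimen, treatment-duration class.
model_design <- function(meta, outcome = c("cd4_pre", "cd4_post")) {
  outcome <- match.arg(outcome)
  cols <- list(
    female = as.integer(meta$gender == "female"),
    age = as.numeric(meta$age),
    minority = as.integer(meta$ethnicity != "Han"),
    trans_homosexual = as.integer(meta$transmission == "homosexual"),
    trans_other = as.integer(!meta$transmission %in%
                               c("heterosexual", "homosexual"))
  )
  if (outcome == "cd4_pre") {
    y <- as.numeric(meta$cd4_pre)
  } else {
    for (col in c("cd4_post", "regimen", "duration_class")) {
      if (is.null(meta[[col]])) stop("metadata missing column ", col)
    }
    y <- as.numeric(meta$cd4_post)
    cols$cd4_pre <- as.numeric(meta$cd4_pre)
    cols$regimen_d4t <- as.integer(meta$regimen == "EFV/NVP+3TC+d4T")
    cols$regimen_other <- as.integer(!meta$regimen %in%
                                       c("EFV/NVP+3TC+AZT",
                                         "EFV/NVP+3TC+d4T"))
    cols$duration_ge3 <- as.integer(meta$duration_class == ">=3")
  }
  Xc <- cbind(intercept = 1, do.call(cbind, cols))
  ok <- stats::complete.cases(Xc) & !is.na(y)
  list(y = y[ok], covariates = Xc[ok, , drop = FALSE], ids = meta$id[ok])
}

# Deterministic per-substitution seed stream derived from the master
# seed and the column key, so scan results are column-order invariant.
column_seed <- function(master_seed, key, outcome = "") {
  chars <- utf8ToInt(paste0(key, "#", outcome))
  h <- 0
  for (c in chars) h <- (h * 31 + c) %% 2147483647
  (h + (master_seed %% 2147483647) * 10007) %% 2147483647
}

#' Run the substitution-by-substitution association scan
#'
#' For each substitution column and each requested outcome, fits a
#' median regression of the outcome on carrier status plus the
#' outcome-specific covariates, with case-resampling bootstrap
#' inference. The Bonferroni threshold is `alpha / (total tests)` where
#' the total counts every fitted model (kept columns x outcomes).
#'
#' The prevalence filter is applied to the rows that are complete cases
#' for the *last* requested outcome (the post-treatment model when both
#' are run), and the same kept substitution set is used for every
#' outcome, mirroring a design in which the filter is defined on the
#' follow-up cohort.
#'
#' @param matrix Binary genotype matrix (participants x substitutions).
#' @param meta Participant metadata with the covariate columns.
#' @param outcomes Character vector among `"cd4_pre"`, `"cd4_post"`.
#' @param B Bootstrap replications per model (default 1000).
#' @param seed Master seed; per-substitution streams are derived from it
#'   and the column key.
#' @param alpha Family-wise significance level (default 0.05).
#' @param low,high Prevalence-filter bounds.
#' @param ref Optional `mito_reference` used to label each
#'   substitution's region in the results.
#' @return Object of class `mito_scan`: list with `results` (data frame
#'   sorted by p: substitution, region, outcome, n, carriers, beta, se,
#'   ci_lower, ci_upper, t, p, significant_bonferroni), `n_tests`,
#'   `threshold`, `n_kept`, `filter_n` and the call parameters.
#' @export
run_scan <- function(matrix, meta, outcomes = c("cd4_pre", "cd4_post"),
                     B = 1000L, seed = 1L, alpha = 0.05,
                     low = 0.01, high = 0.99, ref = NULL) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  designs <- lapply(outcomes, function(o) model_design(meta, o))
  names(designs) <- outcomes

  # filter on the last outcome's complete cases (follow-up cohort)
  basis_ids <- intersect(rownames(matrix),
                         designs[[length(designs)]]$ids)
  if (length(basis_ids) == 0L) stop("no participants shared by genotype ",
                                    "matrix and phenotype table")
  Gf <- prevalence_filter(matrix[basis_ids, , drop = FALSE], low, high)
  kept <- colnames(Gf)
  n_tests <- length(kept) * length(outcomes)
  threshold <- alpha / n_tests

  region_of_key <- function(key) {
    if (is.null(ref)) return(NA_character_)
    pos <- as.integer(sub("^m\\.([0-9]+).*$", "\\1", key))
    reg <- region_of(pos, ref)
    if (nrow(reg) == 0L) "non-coding" else
      paste(unique(reg$gene), collapse = "/")
  }

  rows <- list()
  for (o in outcomes) {
    d <- designs[[o]]
    ids <- intersect(rownames(matrix), d$ids)
    sel <- match(ids, d$ids)
    yv <- d$y[sel]
    covar <- d$covariates[sel, , drop = FALSE]
    # a covariate level absent from the analysis subset yields a
    # constant (all-zero) dummy; drop it rather than fail every model
    constant <- apply(covar, 2, function(col) stats::var(col) == 0)
    constant["intercept"] <- FALSE
    if (any(constant)) {
      message("dropping constant covariate column(s) for ", o, ": ",
              paste(colnames(covar)[constant], collapse = ", "))
      covar <- covar[, !constant, drop = FALSE]
    }
    for (key in kept) {
      g <- matrix[ids, key]
      X <- cbind(covar[, "intercept", drop = FALSE], carrier = g,
                 covar[, setdiff(colnames(covar), "intercept"),
                       drop = FALSE])
      inf <- bootstrap_inference(yv, X, B = B,
                                 seed = column_seed(seed, key, o),
                                 term = "carrier")
      rows[[length(rows) + 1L]] <- data.frame(
        substitution = key, region = region_of_key(key), outcome = o,
        n = length(yv), carriers = sum(g),
        beta = inf$beta, se = inf$se,
        ci_lower = inf$ci_lower, ci_upper = inf$ci_upper,
        t = inf$t, p = inf$p,
        stringsAsFactors = FALSE
      )
    }
  }
  results <- do.call(rbind, rows)
  results$significant_bonferroni <- !is.na(results$p) &
    results$p < threshold
  results <- results[order(results$p), , drop = FALSE]
  rownames(results) <- NULL
  structure(
    list(results = results, n_tests = n_tests, threshold = threshold,
         n_kept = length(kept), filter_n = length(basis_ids),
         kept_range = attr(Gf, "kept_range"), B = B, seed = seed,
         alpha = alpha),
    class = "mito_scan"
  )
}

#' @export
print.mito_scan <- function(x, ...) {
  cat("<mito_scan> ", x$n_kept, " substitutions, ", x$n_tests,
      " tests, Bonferroni threshold ", format(x$threshold, digits = 3),
      "\n", sep = "")
  sig <- x$results[x$results$significant_bonferroni, , drop = FALSE]
  cat("  significant: ", nrow(sig), "\n", sep = "")
  invisible(x)
}
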