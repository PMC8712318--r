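# Gender x age-group x immune-level stratification and the trend /
# comparison statistics run across subpopulations.

.AGE_GROUPS <- c("17-29", "30-44", "45-59", ">=60")

#' Age group of the four-level ordinal classification
#'
#' @param age Age in years.
#' @return Factor with levels `17-29`, `30-44`, `45-59`, `>=60`.
#' @export
age_group_of <- function(age) {
  cut(age, breaks = c(-Inf, 29, 44, 59, Inf), labels = .AGE_GROUPS,
      right = TRUE)
}

#' Immune level at the 200 cells/ul CD4 cut
#'
#' @param cd4 Pre-treatment CD4+ T-cell count (cells/ul).
#' @return Factor `severe` (< 200) / `mild` (>= 200).
#' @export
immune_level_of <- function(cd4) {
  factor(ifelse(cd4 < 200, "severe", "mild"), levels = c("severe", "mild"))
}

#' Read a participant metadata table
#'
#' Tab-delimited text with at least `id`, `gender`, `age`, `ethnicity`,
#' `transmission` and `cd4_pre`; optionally `cd4_post`, `regimen`,
#' `duration_months` and `haplogroup`. Derived columns (`age_group`,
#' `immune_level`, `duration_class`) are added if absent.
#'
#' @param path File path.
#' @return Data frame of participant records.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#")
  req <- c("id", "gender", "age", "ethnicity", "transmission", "cd4_pre")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  complete_metadata(meta)
}

# Fill derived columns and validate consistency.
complete_metadata <- function(meta) {
  if (anyDuplicated(meta$id)) stop("duplicate participant id(s)")
  if (!all(meta$gender %in% c("male", "female"))) {
    stop("gender must be 'male' or 'female'")
  }
  meta$age_group <- as.character(age_group_of(meta$age))
  meta$immune_level <- as.character(immune_level_of(meta$cd4_pre))
  if (!is.null(meta$duration_months) && is.null(meta$duration_class)) {
    meta$duration_class <- ifelse(is.na(meta$duration_months), NA,
                                  ifelse(meta$duration_months < 3, "<3",
                                         ">=3"))
  }
  meta
}

#' Stratify a cohort into the 16 gender x age x immune subpopulations
#'
#' Builds the 2 (gender) x 4 (age group) x 2 (immune level) = 16 strata.
#' Participants not matching the ethnicity filter are excluded before
#' stratification; strata with fewer than `min_size` members are flagged
#' but kept.
#'
#' @param meta Participant metadata (see [read_metadata()]).
#' @param ethnicity Keep only this ethnicity (default `"Han"`; `NULL`
#'   disables the filter).
#' @param min_size Minimum acceptable stratum size (default 5).
#' @return Object of class `mito_strata`: list with `table` (one row per
#'   stratum: gender, age_group, immune_level, n, below_min), `members`
#'   (named list of participant id vectors) and `n_total`.
#' @export
stratify <- function(meta, ethnicity = "Han", min_size = 5L) {
  if (nrow(meta) == 0L) stop("empty cohort")
  meta <- complete_metadata(meta)
  if (!is.null(ethnicity)) {
    meta <- meta[meta$ethnicity == ethnicity, , drop = FALSE]
    if (nrow(meta) == 0L) stop("no participants left after ethnicity filter")
  }
  grid <- expand.grid(gender = c("male", "female"),
                      age_group = .AGE_GROUPS,
                      immune_level = c("severe", "mild"),
                      stringsAsFactors = FALSE)
  key <- function(g, a, i) paste(g, a, i, sep = "|")
  meta_key <- key(meta$gender, meta$age_group, meta$immune_level)
  members <- lapply(seq_len(nrow(grid)), function(r) {
    meta$id[meta_key == key(grid$gender[r], grid$age_group[r],
                            grid$immune_level[r])]
  })
  names(members) <- key(grid$gender, grid$age_group, grid$immune_level)
  grid$n <- vapply(members, length, 1L)
  grid$below_min <- grid$n < min_size
  structure(
    list(table = grid, members = members, n_total = nrow(meta),
         min_size = min_size),
    class = "mito_strata"
  )
}

#' @export
print.mito_strata <- function(x, ...) {
  cat("<mito_strata> ", nrow(x$table), " strata over ", x$n_total,
      " participants (", sum(x$table$below_min), " below size ",
      x$min_size, ")\n", sep = "")
  invisible(x)
}

#' Age-related linear trend of a metric across ordinal age groups
#'
#' Ordinary least squares of the per-age-group metric values against
#' ordinal age-group codes (1, 2, 3, 4 by default).
#'
#' @param values Metric values per age group (NAs allowed).
#' @param codes Ordinal codes (default `seq_along(values)`).
#' @return List with `beta`, `intercept`, `p` (two-sided, from the
#'   slope t-test) and `r_squared`.
#' @export
#' @examples
#' age_trend(c(1, 2, 3, 4))$beta  # 1
age_trend <- function(values, codes = seq_along(values)) {
  ok <- !is.na(values) & !is.na(codes)
  if (sum(ok) < 3L) stop("need >= 3 non-missing age-group values")
  xv <- as.numeric(codes[ok]); yv <- as.numeric(values[ok])
  n <- length(xv)
  beta <- sum((xv - mean(xv)) * (yv - mean(yv))) / sum((xv - mean(xv))^2)
  intercept <- mean(yv) - beta * mean(xv)
  fitted <- intercept + beta * xv
  ss_res <- sum((yv - fitted)^2)
  ss_tot <- sum((yv - mean(yv))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  df <- n - 2L
  se <- sqrt(ss_res / df / sum((xv - mean(xv))^2))
  p <- if (se == 0) as.numeric(ss_res == 0 & beta != 0) * 0 else
    2 * stats::pt(-abs(beta / se), df)
  list(beta = beta, intercept = intercept, p = p, r_squared = r2)
}

#' Compare bias-density distributions between two subpopulations
#'
#' Two-sided Wilcoxon rank-sum test (exact for small tie-free samples,
#' tie-corrected normal approximation otherwise), as used to compare
#' amino-acid-change bias densities between severe- and
#' mild-immunodeficiency subpopulations.
#'
#' @param group_a,group_b Numeric vectors.
#' @return List with `statistic` (rank-sum W), `p` and `method`.
#' @export
compare_bias_density <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be nonempty")
  }
  ht <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p = ht$p.value, method = ht$method)
}

#' Welch two-sample comparison of per-sample substitution counts
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' as used to check that two sequencing platforms yield comparable
#' substitution loads.
#'
#' @param counts_a,counts_b Per-sample substitution counts.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
platform_comparison <- function(counts_a, counts_b) {
  if (length(counts_a) < 2L || length(counts_b) < 2L) {
    stop("both samples must have size >= 2")
  }
  if (stats::var(counts_a) == 0 && stats::var(counts_b) == 0) {
    if (mean(counts_a) == mean(counts_b)) {
      return(list(t = 0, df = NA_real_, p = 1,
                  mean_a = mean(counts_a), mean_b = mean(counts_b)))
    }
    stop("degenerate variance in both groups")
  }
  ht <- stats::t.test(counts_a, counts_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_a = mean(counts_a), mean_b = mean(counts_b))
}

#' Per-stratum metric table and age trends
#'
#' Computes a per-macrodivision diversity-density table for every
#' stratum and, within each (gender, immune level) family, the
#' age-related trend of each macrodivision's diversity density across
#' the four ordinal age groups.
#'
#' @param x A `mito_calls` object.
#' @param meta Participant metadata covering the called samples.
#' @param ref The `mito_reference`.
#' @param ethnicity,min_size Passed to [stratify()].
#' @return List with `strata` (the [stratify()] object), `metrics`
#'   (long data frame: stratum x unit diversity densities) and `trends`
#'   (data frame: gender, immune_level, unit, metric, beta, p).
#' @export
stratum_age_trends <- function(x, meta, ref, ethnicity = "Han",
                               min_size = 5L) {
  st <- stratify(meta, ethnicity, min_size)
  tabs <- list()
  for (k in seq_len(nrow(st$table))) {
    ids <- intersect(st$members[[k]], x$samples)
    if (length(ids) == 0L) next
    dd <- diversity_density_table(x, ref, "macrodivision", samples = ids)
    dd$gender <- st$table$gender[k]
    dd$age_group <- st$table$age_group[k]
    dd$immune_level <- st$table$immune_level[k]
    tabs[[length(tabs) + 1L]] <- dd
  }
  metrics <- do.call(rbind, tabs)
  trends <- list()
  metric_cols <- c(all = "diversity_density",
                   synonymous = "diversity_density_synonymous",
                   nonsynonymous = "diversity_density_nonsynonymous")
  for (g in c("male", "female")) {
    for (im in c("severe", "mild")) {
      sub <- metrics[metrics$gender == g & metrics$immune_level == im, ,
                     drop = FALSE]
      for (unit in unique(sub$unit)) {
        for (mc in names(metric_cols)) {
          vals <- vapply(.AGE_GROUPS, function(a) {
            v <- sub[[metric_cols[mc]]][sub$unit == unit &
                                          sub$age_group == a]
            if (length(v) == 0L) NA_real_ else v[1]
          }, numeric(1))
          if (sum(!is.na(vals)) < 3L) next
          tr <- age_trend(vals, codes = 1:4)
          trends[[length(trends) + 1L]] <- data.frame(
            gender = g, immune_level = im, unit = unit, metric = mc,
            beta = tr$beta, p = tr$p, r_squared = tr$r_squared,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  list(strata = st, metrics = metrics,
       trends = if (length(trends)) do.call(rbind, trends) else NULL)
}
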