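# Cohort-level mutational characterization metrics: diversity, volume,
# densities, relative diversity, momentum, amino-acid change bias and
# physicochemical-change prevalences.

filter_calls <- function(x, samples = NULL) {
  if (is.null(samples)) return(x$calls)
  missing <- setdiff(samples, x$samples)
  if (length(missing) > 0L) {
    stop("unknown sample id(s): ", paste(utils::head(missing, 5L),
                                         collapse = ", "))
  }
  x$calls[x$calls$sample_id %in% samples, , drop = FALSE]
}

# (type, unit) assignment table for a grouping level, one row per
# distinct pair; carries per-unit synonymy class flags.
type_units <- function(x, grouping) {
  ga <- x$gene_annotations
  reg <- x$registry
  if (grouping == "genome") {
    tu <- data.frame(m_notation = reg$m_notation, unit = "genome",
                     stringsAsFactors = FALSE)
  } else {
    unit <- if (grouping == "gene") ga$gene else ga$macrodivision
    tu <- unique(data.frame(m_notation = ga$m_notation, unit = unit,
                            stringsAsFactors = FALSE))
    inter <- reg$m_notation[reg$n_genes == 0L]
    if (length(inter) > 0L) {
      tu <- rbind(tu, data.frame(m_notation = inter, unit = "intergenic",
                                 stringsAsFactors = FALSE))
    }
  }
  # class flags aggregated over the type's annotation rows within a unit
  key <- paste(ga$m_notation, if (grouping == "gene") ga$gene else
    if (grouping == "macrodivision") ga$macrodivision else "genome")
  syn <- tapply(ga$synonymy == "synonymous", key, any, default = FALSE)
  nsyn <- tapply(ga$synonymy == "nonsynonymous", key, any, default = FALSE)
  tkey <- paste(tu$m_notation, tu$unit)
  tu$synonymous <- !is.na(syn[tkey]) & syn[tkey]
  tu$nonsynonymous <- !is.na(nsyn[tkey]) & nsyn[tkey]
  tu$synonymous[is.na(tu$synonymous)] <- FALSE
  tu$nonsynonymous[is.na(tu$nonsynonymous)] <- FALSE
  tu
}

#' Mutational diversity and volume per region
#'
#' Diversity is the number of distinct variant types (keyed by position,
#' ref, alt and kind) observed in a unit; volume is the total number of
#' variant calls (carrier-weighted). At the individual scale the two are
#' equal. A type inside two overlapping genes contributes to each gene,
#' but only once to a shared macrodivision or to the genome total.
#'
#' @param x A `mito_calls` object.
#' @param grouping `"macrodivision"`, `"gene"` or `"genome"`.
#' @param samples Optional character vector restricting the cohort.
#' @return Data frame with columns `unit`, `diversity`, `volume`,
#'   `diversity_synonymous`, `diversity_nonsynonymous`,
#'   `diversity_indel` and `n_samples`.
#' @export
diversity_and_volume <- function(x, grouping = c("macrodivision", "gene",
                                                 "genome"),
                                 samples = NULL) {
  grouping <- match.arg(grouping)
  calls <- filter_calls(x, samples)
  if (nrow(calls) == 0L) {
    return(data.frame(unit = character(), diversity = integer(),
                      volume = integer(), diversity_synonymous = integer(),
                      diversity_nonsynonymous = integer(),
                      diversity_indel = integer(), n_samples = integer(),
                      stringsAsFactors = FALSE))
  }
  n_samples <- if (is.null(samples)) x$n_samples else length(samples)
  carriers <- table(calls$m_notation)
  present <- names(carriers)

  tu <- type_units(x, grouping)
  tu <- tu[tu$m_notation %in% present, , drop = FALSE]
  tu$carriers <- as.integer(carriers[tu$m_notation])
  reg <- x$registry
  tu$indel <- reg$kind[match(tu$m_notation, reg$m_notation)] != "substitution"

  units <- sort(unique(tu$unit))
  out <- data.frame(
    unit = units,
    diversity = as.integer(tapply(tu$m_notation, tu$unit, length)[units]),
    volume = as.integer(tapply(tu$carriers, tu$unit, sum)[units]),
    diversity_synonymous =
      as.integer(tapply(tu$synonymous, tu$unit, sum)[units]),
    diversity_nonsynonymous =
      as.integer(tapply(tu$nonsynonymous, tu$unit, sum)[units]),
    diversity_indel = as.integer(tapply(tu$indel, tu$unit, sum)[units]),
    n_samples = n_samples,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Diversity density
#'
#' Diversity divided by the subpopulation sample size and by the unit
#' length in kilobase pairs.
#'
#' @param diversity Number of distinct types (vectorised).
#' @param n_samples Subpopulation sample size (> 0).
#' @param unit_length_kb Unit length in kb (> 0).
#' @return `diversity / n_samples / unit_length_kb`.
#' @export
diversity_density <- function(diversity, n_samples, unit_length_kb) {
  if (any(n_samples <= 0)) stop("n_samples must be positive")
  if (any(unit_length_kb <= 0)) stop("unit_length_kb must be positive")
  diversity / n_samples / unit_length_kb
}

#' Per-macrodivision (or per-gene) diversity-density table
#'
#' @inheritParams diversity_and_volume
#' @param ref The `mito_reference` providing unit lengths.
#' @return The [diversity_and_volume()] table with `length_kb`,
#'   `diversity_density`, `diversity_density_synonymous` and
#'   `diversity_density_nonsynonymous` columns appended (intergenic
#'   positions have no defined unit length and are dropped).
#' @export
diversity_density_table <- function(x, ref,
                                    grouping = c("macrodivision", "gene"),
                                    samples = NULL) {
  grouping <- match.arg(grouping)
  dv <- diversity_and_volume(x, grouping, samples)
  lens <- if (grouping == "macrodivision") macrodivision_lengths(ref) else
    gene_lengths(ref)
  dv <- dv[dv$unit %in% names(lens), , drop = FALSE]
  dv$length_kb <- as.numeric(lens[dv$unit]) / 1000
  dv$diversity_density <-
    diversity_density(dv$diversity, dv$n_samples, dv$length_kb)
  dv$diversity_density_synonymous <-
    diversity_density(dv$diversity_synonymous, dv$n_samples, dv$length_kb)
  dv$diversity_density_nonsynonymous <-
    diversity_density(dv$diversity_nonsynonymous, dv$n_samples, dv$length_kb)
  dv
}

# Observed distinct definite substitution types per protein gene and
# class. Classes: all, synonymous, nonsynonymous, transition,
# transversion (the latter two restricted to classified coding
# positions, consistent with the possible-substitution space).
observed_definite_by_gene <- function(x, samples = NULL) {
  calls <- filter_calls(x, samples)
  present <- unique(calls$m_notation)
  ga <- x$gene_annotations
  reg <- x$registry
  ga <- ga[ga$m_notation %in% present & ga$gene_kind == "protein" &
             ga$kind == "substitution", , drop = FALSE]
  ga <- ga[!is.na(ga$synonymy) & ga$synonymy %in%
             c("synonymous", "nonsynonymous"), , drop = FALSE]
  ga$transition <- reg$transition[match(ga$m_notation, reg$m_notation)]
  genes <- sort(unique(ga$gene))
  out <- data.frame(
    gene = genes,
    all = as.integer(tapply(ga$m_notation, ga$gene, length)[genes]),
    synonymous = as.integer(
      tapply(ga$synonymy == "synonymous", ga$gene, sum)[genes]),
    nonsynonymous = as.integer(
      tapply(ga$synonymy == "nonsynonymous", ga$gene, sum)[genes]),
    transition = as.integer(tapply(ga$transition, ga$gene, sum)[genes]),
    transversion = as.integer(tapply(!ga$transition, ga$gene, sum)[genes]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Relative diversity
#'
#' Observed number of distinct definite substitution types relative to
#' all possible substitutions deduced from the genetic code and the
#' reference, per class.
#'
#' @param observed Observed count(s) of distinct definite types.
#' @param possible Corresponding possible count(s) from
#'   [enumerate_substitution_space()].
#' @return `observed / possible` (0 where `possible` is 0).
#' @export
#' @examples
#' relative_diversity(1075, 8291)  # 0.1297 (13.0%)
relative_diversity <- function(observed, possible) {
  if (any(observed < 0) || any(possible < 0)) stop("counts must be >= 0")
  if (any(observed > possible)) {
    stop("observed exceeds possible: classification bug upstream")
  }
  ifelse(possible == 0, 0, observed / possible)
}

#' Per-gene and genome-wide relative-diversity table
#'
#' @param x A `mito_calls` object.
#' @param space A `substitution_space` for the same reference.
#' @param samples Optional cohort restriction.
#' @return Data frame: one row per protein gene plus a `total` row, with
#'   observed counts and relative diversities for the classes all /
#'   synonymous / nonsynonymous / transition / transversion. Totals are
#'   per-gene sums, matching the per-gene summation convention of the
#'   possible-substitution space.
#' @export
relative_diversity_table <- function(x, space, samples = NULL) {
  obs <- observed_definite_by_gene(x, samples)
  pg <- space$per_gene
  genes <- pg$gene
  get <- function(col) {
    v <- obs[[col]][match(genes, obs$gene)]
    ifelse(is.na(v), 0L, v)
  }
  out <- data.frame(
    gene = c(genes, "total"),
    observed_all = c(get("all"), sum(get("all"))),
    observed_synonymous = c(get("synonymous"), sum(get("synonymous"))),
    observed_nonsynonymous = c(get("nonsynonymous"),
                               sum(get("nonsynonymous"))),
    observed_transition = c(get("transition"), sum(get("transition"))),
    observed_transversion = c(get("transversion"), sum(get("transversion"))),
    possible_synonymous = c(pg$possible_synonymous,
                            sum(pg$possible_synonymous)),
    possible_nonsynonymous = c(pg$possible_nonsynonymous,
                               sum(pg$possible_nonsynonymous)),
    possible_transitions = c(pg$possible_transitions,
                             sum(pg$possible_transitions)),
    possible_transversions = c(pg$possible_transversions,
                               sum(pg$possible_transversions)),
    stringsAsFactors = FALSE
  )
  out$relative_synonymous <-
    relative_diversity(out$observed_synonymous, out$possible_synonymous)
  out$relative_nonsynonymous <-
    relative_diversity(out$observed_nonsynonymous,
                       out$possible_nonsynonymous)
  out$relative_all <- relative_diversity(
    out$observed_all, out$possible_synonymous + out$possible_nonsynonymous)
  out$relative_transition <-
    relative_diversity(out$observed_transition, out$possible_transitions)
  out$relative_transversion <-
    relative_diversity(out$observed_transversion, out$possible_transversions)
  out
}

#' Mutational momentum
#'
#' The ordinary-least-squares slope of the per-gene observed number of
#' distinct definite substitutions of a class divided by the sample
#' size, against the per-gene maximum possible number of substitutions
#' of that class, across the protein-coding genes (intercept included).
#'
#' @param observed_per_gene Named vector (gene -> observed distinct
#'   definite types of the class).
#' @param n_samples Subpopulation sample size.
#' @param space A `substitution_space`.
#' @param class `"synonymous"` or `"nonsynonymous"`.
#' @return List with `beta` (the momentum slope), `intercept`,
#'   `r_squared` and `n_genes`.
#' @export
momentum <- function(observed_per_gene, n_samples, space,
                     class = c("synonymous", "nonsynonymous")) {
  class <- match.arg(class)
  pg <- space$per_gene
  poss <- stats::setNames(
    pg[[paste0("possible_", class)]], pg$gene)
  genes <- intersect(names(poss), names(observed_per_gene))
  if (length(genes) < 3L) stop("need >= 3 genes with defined values")
  xv <- as.numeric(poss[genes])
  yv <- as.numeric(observed_per_gene[genes]) / n_samples
  if (stats::var(xv) == 0) stop("degenerate predictor: all possible counts equal")
  beta <- stats::cov(xv, yv) / stats::var(xv)
  intercept <- mean(yv) - beta * mean(xv)
  fitted <- intercept + beta * xv
  ss_res <- sum((yv - fitted)^2)
  ss_tot <- sum((yv - mean(yv))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(beta = beta, intercept = intercept, r_squared = r2,
       n_genes = length(genes))
}

# Convenience: momentum of a cohort subset straight from calls.
momentum_from_calls <- function(x, space,
                                class = c("synonymous", "nonsynonymous"),
                                samples = NULL) {
  class <- match.arg(class)
  obs <- observed_definite_by_gene(x, samples)
  n <- if (is.null(samples)) x$n_samples else length(samples)
  momentum(stats::setNames(obs[[class]], obs$gene), n, space, class)
}

#' Amino-acid change matrix, bias and bias density
#'
#' Tabulates the distinct amino-acid changes implied by definite
#' nonsynonymous substitution types (changes involving stop codons are
#' excluded; a type inside two overlapping genes contributes the change
#' implied by each gene). Bias for a target amino acid is the observed
#' number of changes to it relative to the maximum possible number of
#' changes to it (the `aa_max` denominators of the substitution space);
#' bias density additionally divides the observed count by the sample
#' size.
#'
#' @param x A `mito_calls` object.
#' @param space A `substitution_space`.
#' @param samples Optional cohort restriction.
#' @param weighted If `TRUE`, weight changes by carrier counts instead
#'   of counting distinct types.
#' @return Object of class `aa_change_matrix`: list with `matrix`
#'   (20 x 20 observed counts, rows = source, columns = target amino
#'   acid, zero diagonal), `observed_to`, `max_to`, `bias`,
#'   `bias_density` (named 20-vectors) and `n_samples`.
#' @export
amino_acid_changes <- function(x, space, samples = NULL, weighted = FALSE) {
  calls <- filter_calls(x, samples)
  n_samples <- if (is.null(samples)) x$n_samples else length(samples)
  carriers <- table(calls$m_notation)
  ga <- x$gene_annotations
  reg <- x$registry
  ga <- ga[ga$m_notation %in% names(carriers) &
             reg$definite[match(ga$m_notation, reg$m_notation)] &
             !is.na(ga$synonymy) & ga$synonymy == "nonsynonymous" &
             ga$aa_ref %in% .AA20 & ga$aa_alt %in% .AA20, , drop = FALSE]
  m <- matrix(0, 20L, 20L, dimnames = list(.AA20, .AA20))
  if (nrow(ga) > 0L) {
    w <- if (weighted) as.numeric(carriers[ga$m_notation]) else
      rep(1, nrow(ga))
    for (i in seq_len(nrow(ga))) {
      m[ga$aa_ref[i], ga$aa_alt[i]] <- m[ga$aa_ref[i], ga$aa_alt[i]] + w[i]
    }
  }
  observed_to <- colSums(m)
  max_to <- space$aa_max[.AA20]
  bias <- ifelse(max_to == 0, 0, observed_to / max_to)
  bias_density <- ifelse(max_to == 0, 0, (observed_to / n_samples) / max_to)
  structure(
    list(matrix = m, observed_to = observed_to, max_to = max_to,
         bias = bias, bias_density = bias_density, n_samples = n_samples),
    class = "aa_change_matrix"
  )
}

#' @export
print.aa_change_matrix <- function(x, ...) {
  cat("<aa_change_matrix> ", sum(x$matrix), " observed amino-acid changes",
      " over ", x$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Physicochemical property changes of amino-acid replacements
#'
#' Maps the observed amino-acid change matrix onto a physicochemical
#' class scheme and reports the prevalence of each ordered class pair.
#'
#' @param aam An [amino_acid_changes()] result.
#' @param scheme One of the schemes in [aa_class_schemes()]
#'   (e.g. `"acidity_polarity"`, `"hydropathy"`, `"volume"`,
#'   `"chemical"`, `"charge"`, `"hydrogen_bond"`, `"polarity"`).
#' @param classes Class assignment table, by default the bundled one.
#' @return Data frame with `from_class`, `to_class`, `count`, `percent`
#'   (percentages sum to 100) and `density` (count / sample size).
#' @export
physicochemical_changes <- function(aam, scheme,
                                    classes = aa_class_schemes()) {
  cls <- aa_classes_for_scheme(scheme, classes)
  m <- aam$matrix
  from_cls <- cls[rownames(m)]
  to_cls <- cls[colnames(m)]
  if (any(is.na(from_cls)) || any(is.na(to_cls))) {
    stop("scheme '", scheme, "' does not cover all 20 amino acids")
  }
  levels_ <- unique(cls)
  agg <- matrix(0, length(levels_), length(levels_),
                dimnames = list(levels_, levels_))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] > 0) {
        agg[from_cls[i], to_cls[j]] <- agg[from_cls[i], to_cls[j]] + m[i, j]
      }
    }
  }
  total <- sum(agg)
  out <- data.frame(
    from_class = rep(rownames(agg), times = ncol(agg)),
    to_class = rep(colnames(agg), each = nrow(agg)),
    count = as.vector(agg),
    stringsAsFactors = FALSE
  )
  out$percent <- if (total == 0) 0 else 100 * out$count / total
  out$density <- out$count / aam$n_samples
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}
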