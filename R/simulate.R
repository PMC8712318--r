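# Fully synthetic cohorts: a stand-in reference genome, planted
# variants, Table-1-style participant metadata and CD4 outcomes drawn
# from a linear model with heavy-tailed noise.

.AMBIG_CODE <- c("AG" = "R", "GA" = "R", "CT" = "Y", "TC" = "Y",
                 "CG" = "S", "GC" = "S", "AT" = "W", "TA" = "W",
                 "GT" = "K", "TG" = "K", "AC" = "M", "CA" = "M")

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

rlaplace <- function(n, scale) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

#' Generate the synthetic stand-in reference genome
#'
#' Builds a 16,569-bp sequence on the canonical mitochondrial gene
#' annotation: background bases are drawn from the human mtDNA base
#' composition, every protein gene gets a start codon, sense codons
#' free of internal stops (where gene overlaps permit), a proper
#' terminal stop or incomplete stop, and the position-3107 placeholder
#' is set to N. The SEQUENCE IS SYNTHETIC: coordinates and gene
#' structure are real, nucleotide content is not, so sequence-dependent
#' statistics differ from the real reference.
#'
#' @param seed Seed making the construction deterministic.
#' @return A `mito_reference` of length 16,569.
#' @export
make_synthetic_reference <- function(seed = 20211214L) {
  feats_path <- system.file("extdata", "rCRS_features.tsv",
                            package = "mitocohort")
  if (feats_path == "") feats_path <- file.path("inst", "extdata",
                                                "rCRS_features.tsv")
  features <- utils::read.delim(feats_path, stringsAsFactors = FALSE,
                                comment.char = "#")
  with_seed(seed, {
    comp <- c(A = 0.309, C = 0.313, G = 0.131, T = 0.247)
    chars <- sample(names(comp), .MITO_LENGTH, replace = TRUE, prob = comp)
    claimed <- logical(.MITO_LENGTH)
    stops <- c("TAA", "TAG", "AGA", "AGG")
    sense <- setdiff(names(.MITO_CODE), stops)

    write_codon <- function(positions, codon, strand) {
      bases <- strsplit(codon, "", fixed = TRUE)[[1]]
      if (strand == "light") bases <- unname(.COMPLEMENT[bases])
      chars[positions] <<- bases
    }
    read_codon <- function(positions, strand) {
      bases <- chars[positions]
      if (strand == "light") bases <- unname(.COMPLEMENT[bases])
      paste(bases, collapse = "")
    }

    prot <- features[features$kind == "protein", , drop = FALSE]
    prot <- prot[order(prot$start), , drop = FALSE]
    for (i in seq_len(nrow(prot))) {
      strand <- prot$strand[i]
      inc <- prot$incomplete_stop[i]
      pos <- if (strand == "heavy") prot$start[i]:prot$end[i] else
        prot$end[i]:prot$start[i]
      ncod <- (length(pos) - inc) %/% 3L
      for (k in seq_len(ncod)) {
        cp <- pos[(3L * k - 2L):(3L * k)]
        free <- !claimed[cp]
        codon <- read_codon(cp, strand)
        if (k == 1L) {
          if (all(free)) write_codon(cp, "ATG", strand)
        } else if (k == ncod && inc == 0L) {
          if (all(free)) write_codon(cp, "TAA", strand)
        } else if (codon %in% stops) {
          if (all(free)) {
            write_codon(cp, sample(sense, 1L), strand)
          } else if (any(free)) {
            # break the stop through one free position
            for (j in which(free)) {
              for (b in c("C", "G", "A", "T")) {
                cand <- codon
                substr(cand, j, j) <- b
                if (!cand %in% stops) {
                  write_codon(cp[j], b, strand)
                  codon <- cand
                  break
                }
              }
              if (!codon %in% stops) break
            }
          }
        }
      }
      if (inc > 0L) {
        tailpos <- pos[(3L * ncod + 1L):length(pos)]
        write_codon(tailpos, substr("TA", 1L, inc), strand)
        claimed[tailpos] <- TRUE
      }
      claimed[pos] <- TRUE
    }
    chars[3107L] <- "N"
    new_mito_reference(paste(chars, collapse = ""), features,
                       check_genome = TRUE)
  })
}

#' Draw a panel of plantable variants
#'
#' Samples substitution (and optionally indel) sites uniformly over the
#' genome, avoiding the N placeholder and duplicate positions; carrier
#' frequencies are log-uniform over `freq_range` and planted outcome
#' effects default to zero.
#'
#' @param ref A `mito_reference`.
#' @param n_substitutions,n_indels Panel sizes.
#' @param freq_range Carrier-frequency range (log-uniform).
#' @param seed Seed.
#' @return Data frame with columns `position`, `ref`, `alt`, `kind`,
#'   `frequency`, `effect`, `m_notation`.
#' @export
sim_variant_panel <- function(ref, n_substitutions = 60L, n_indels = 3L,
                              freq_range = c(0.005, 0.6), seed = 1L) {
  with_seed(seed, {
    ok <- which(ref$bases %in% c("A", "C", "G", "T"))
    ok <- ok[ok > 5L & ok < ref$length - 5L]
    pos <- sort(sample(ok, n_substitutions + n_indels))
    # keep planted events well separated so they cannot interact
    while (length(pos) > 1L && min(diff(pos)) < 8L) {
      pos <- sort(sample(ok, n_substitutions + n_indels))
    }
    kinds <- sample(rep(c("substitution", "indel"),
                        c(n_substitutions, n_indels)))
    rows <- lapply(seq_along(pos), function(i) {
      p <- pos[i]
      rb <- ref$bases[p]
      if (kinds[i] == "substitution") {
        alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
        data.frame(position = p, ref = rb, alt = alt,
                   kind = "substitution", stringsAsFactors = FALSE)
      } else if (stats::runif(1) < 0.5) {
        data.frame(position = p, ref = rb, alt = "-", kind = "deletion",
                   stringsAsFactors = FALSE)
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), 2L, replace = TRUE),
                     collapse = "")
        data.frame(position = p, ref = "-", alt = ins, kind = "insertion",
                   stringsAsFactors = FALSE)
      }
    })
    panel <- do.call(rbind, rows)
    # store indels in their canonical left-aligned representation so the
    # ledger matches what the variant caller reports
    for (i in which(panel$kind != "substitution")) {
      if (panel$kind[i] == "deletion") {
        norm <- normalize_indel(panel$position[i], panel$ref[i],
                                "deletion", ref$bases)
        panel$position[i] <- norm$pos
        panel$ref[i] <- norm$seq
      } else {
        norm <- normalize_indel(panel$position[i], panel$alt[i],
                                "insertion", ref$bases)
        panel$position[i] <- norm$pos
        panel$alt[i] <- norm$seq
      }
    }
    lf <- log(freq_range)
    panel$frequency <- exp(stats::runif(nrow(panel), lf[1], lf[2]))
    panel$effect <- 0
    panel$m_notation <- mapply(m_notation, panel$position, panel$ref,
                               panel$alt, panel$kind, USE.NAMES = FALSE)
    panel
  })
}

#' Simulation configuration for a synthetic cohort
#'
#' Defaults mirror the marginal composition of a large East-Asian
#' HIV-treatment cohort: 74.18% male; age groups 17-29/30-44/45-59/>=60
#' with probabilities 30.14/40.54/18.81/10.51%; 94.51% Han ethnicity;
#' heterosexual/homosexual/other transmission 69.04/28.62/2.34%;
#' zidovudine-based / stavudine-based / other regimens
#' 77.07/16.30/6.63%; 40.33% treated < 3 months; pre-treatment CD4
#' log-normal with median 219 cells/ul (IQR ~ 149-295); follow-up CD4
#' = pre-treatment CD4 + 70 (median change) + planted variant effects +
#' covariate effects + Laplace noise of scale 94 (IQR of the change ~
#' 130 cells/ul), truncated at zero; 724/856 of participants have a
#' follow-up measurement.
#'
#' @param n_participants Cohort size (default 856).
#' @param variants Optional variant panel from [sim_variant_panel()]
#'   (drawn automatically when `NULL`).
#' @param n_substitutions,n_indels Panel sizes when drawing.
#' @param ambiguity_rate Fraction of substitution calls emitted as
#'   IUPAC two-base mixture codes (default 0.04).
#' @param covariates Named list of marginal probabilities (see
#'   defaults).
#' @param outcome Named list: `intercept`, `noise` (`"laplace"` or
#'   `"normal"`), `scale`, `covariate_effects` (named vector over
#'   design columns, e.g. `c(female = -10)`).
#' @param post_rate Fraction with a follow-up CD4 measurement.
#' @param conflict `"error"` or `"resample"` for same-position carrier
#'   clashes.
#' @param seed Master seed.
#' @return Object of class `sim_config` (a list).
#' @export
sim_config <- function(n_participants = 856L, variants = NULL,
                       n_substitutions = 60L, n_indels = 3L,
                       ambiguity_rate = 0.04,
                       covariates = list(
                         male = 0.7418,
                         age_probs = c(0.3014, 0.4054, 0.1881, 0.1051),
                         han = 0.9451,
                         transmission = c(heterosexual = 0.6904,
                                          homosexual = 0.2862,
                                          other = 0.0234),
                         regimen = c("EFV/NVP+3TC+AZT" = 0.7707,
                                     "EFV/NVP+3TC+d4T" = 0.1630,
                                     "others" = 0.0663),
                         duration_lt3 = 0.4033,
                         cd4_meanlog = log(219), cd4_sdlog = 0.506
                       ),
                       outcome = list(intercept = 70, noise = "laplace",
                                      scale = 94,
                                      covariate_effects = NULL),
                       post_rate = 724 / 856, conflict = "error",
                       seed = 1L) {
  if (!is.null(variants)) {
    stopifnot(all(variants$frequency >= 0 & variants$frequency < 1))
  }
  structure(
    list(n_participants = as.integer(n_participants), variants = variants,
         n_substitutions = n_substitutions, n_indels = n_indels,
         ambiguity_rate = ambiguity_rate, covariates = covariates,
         outcome = outcome, post_rate = post_rate, conflict = conflict,
         seed = seed),
    class = "sim_config"
  )
}

#' Simulate a synthetic cohort
#'
#' Draws carrier status per variant independently at its configured
#' frequency, participant covariates from the configured marginals, and
#' CD4 outcomes from the linear model described in [sim_config()].
#' Regenerating with the same config (and seed) is byte-identical.
#'
#' @param config A [sim_config()].
#' @param ref A `mito_reference`.
#' @param sequences If `TRUE`, also materialise each participant's
#'   genome by planting the carried variants (IUPAC codes for ambiguous
#'   calls) into the reference.
#' @return Object of class `mito_cohort_sim`: list with `metadata`,
#'   `carriers` (binary ground-truth matrix), `ambiguous` (logical
#'   matrix marking calls emitted as mixture codes), `variant_panel`,
#'   `sequences` (named character vector or NULL) and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), ref, sequences = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_participants
    panel <- config$variants
    if (is.null(panel)) {
      panel <- sim_variant_panel(ref, config$n_substitutions,
                                 config$n_indels,
                                 seed = stats::runif(1, 1, 2^30))
    }
    if (anyDuplicated(panel$position)) {
      if (config$conflict == "error") {
        stop("variant panel has conflicting variants at one position")
      }
      panel <- panel[!duplicated(panel$position), , drop = FALSE]
    }
    bad <- panel$kind %in% c("substitution", "deletion") &
      substr(panel$ref, 1, 1) != ref$bases[panel$position]
    if (any(bad)) {
      stop("panel ref base mismatch at position(s) ",
           paste(utils::head(panel$position[bad], 5L), collapse = ", "))
    }

    ids <- sprintf("P%04d", seq_len(n))
    k <- nrow(panel)
    carriers <- matrix(stats::rbinom(n * k, 1L,
                                     rep(panel$frequency, each = n)),
                       n, k, dimnames = list(ids, panel$m_notation))
    ambiguous <- matrix(FALSE, n, k, dimnames = dimnames(carriers))
    subs <- panel$kind == "substitution"
    if (config$ambiguity_rate > 0 && any(subs)) {
      amb <- matrix(stats::runif(n * k) < config$ambiguity_rate, n, k)
      ambiguous[, subs] <- (carriers == 1L & amb)[, subs]
    }

    cv <- config$covariates
    age_lo <- c(17, 30, 45, 60); age_hi <- c(29, 44, 59, 79)
    grp <- sample(1:4, n, replace = TRUE, prob = cv$age_probs)
    meta <- data.frame(
      id = ids,
      gender = ifelse(stats::runif(n) < cv$male, "male", "female"),
      age = age_lo[grp] + floor(stats::runif(n) *
                                  (age_hi[grp] - age_lo[grp] + 1)),
      ethnicity = ifelse(stats::runif(n) < cv$han, "Han", "minority"),
      transmission = sample(names(cv$transmission), n, replace = TRUE,
                            prob = cv$transmission),
      cd4_pre = round(stats::rlnorm(n, cv$cd4_meanlog, cv$cd4_sdlog)),
      stringsAsFactors = FALSE
    )
    has_post <- stats::runif(n) < config$post_rate
    meta$regimen <- ifelse(has_post,
                           sample(names(cv$regimen), n, replace = TRUE,
                                  prob = cv$regimen), NA)
    meta$duration_months <- ifelse(
      has_post, ifelse(stats::runif(n) < cv$duration_lt3,
                       sample(1:2, n, replace = TRUE),
                       sample(3:6, n, replace = TRUE)), NA)

    out <- config$outcome
    effect_term <- as.numeric(carriers %*% panel$effect)
    covar_term <- rep(0, n)
    ce <- out$covariate_effects
    if (!is.null(ce)) {
      design <- cbind(female = as.integer(meta$gender == "female"),
                      age = meta$age,
                      minority = as.integer(meta$ethnicity != "Han"))
      for (nm in names(ce)) {
        covar_term <- covar_term + design[, nm] * ce[[nm]]
      }
    }
    noise <- if (identical(out$noise, "normal")) {
      stats::rnorm(n, 0, out$scale)
    } else {
      rlaplace(n, out$scale)
    }
    cd4_post <- pmax(0, round(meta$cd4_pre + out$intercept + effect_term +
                                covar_term + noise))
    meta$cd4_post <- ifelse(has_post, cd4_post, NA)
    meta$haplogroup <- NA_character_
    meta <- complete_metadata(meta)

    seqs <- NULL
    if (sequences) {
      seqs <- vapply(seq_len(n), function(i) {
        carried <- which(carriers[i, ] == 1L)
        if (length(carried) == 0L) return(ref$sequence)
        v <- panel[carried, , drop = FALSE]
        ambi <- ambiguous[i, carried]
        v$alt <- ifelse(
          v$kind == "substitution" & ambi,
          unname(.AMBIG_CODE[paste0(v$ref, v$alt)]), v$alt)
        apply_variants(ref, v)
      }, character(1))
      names(seqs) <- ids
    }

    structure(
      list(metadata = meta, carriers = carriers, ambiguous = ambiguous,
           variant_panel = panel, sequences = seqs, config = config),
      class = "mito_cohort_sim"
    )
  })
}

#' @export
print.mito_cohort_sim <- function(x, ...) {
  cat("<mito_cohort_sim> ", nrow(x$metadata), " participants, ",
      nrow(x$variant_panel), " planted variant types\n", sep = "")
  invisible(x)
}

#' @export
genotype_matrix.mito_cohort_sim <- function(x, ...) {
  subs <- x$variant_panel$kind == "substitution"
  x$carriers[, subs, drop = FALSE]
}

#' Write a synthetic cohort to disk
#'
#' Emits `cohort.fasta` (when sequences were generated),
#' `metadata.tsv`, the ground-truth `ledger.tsv` (per-variant carriers
#' and effects) and a `config.txt` echo.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim$sequences)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$sequences),
      file.path(dir, "cohort.fasta"))
  }
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ledger <- data.frame(sim$variant_panel,
                       n_carriers = colSums(sim$carriers),
                       stringsAsFactors = FALSE)
  utils::write.table(ledger, file.path(dir, "ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(utils::capture.output(utils::str(sim$config)),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Standing test fixtures
#'
#' Deterministically constructs the small synthetic objects used
#' throughout the test suite: an identity genome, single-substitution /
#' indel / ambiguity genomes, a 16-strata mini-cohort with at least
#' five members per stratum, a null association cohort and a
#' planted-effect cohort.
#'
#' @param ref A `mito_reference`.
#' @param seed Seed.
#' @return Named list of fixtures.
#' @export
make_fixture_suite <- function(ref, seed = 20211214L) {
  with_seed(seed, {
    b100 <- ref$bases[100]
    alt100 <- setdiff(c("A", "C", "G", "T"), b100)[1]
    single <- data.frame(position = 100L, ref = b100, alt = alt100,
                         kind = "substitution", stringsAsFactors = FALSE)
    indel <- data.frame(
      position = c(2000L, 4000L),
      ref = c(paste(ref$bases[2000:2001], collapse = ""), "-"),
      alt = c("-", "TT"),
      kind = c("deletion", "insertion"), stringsAsFactors = FALSE)
    b500 <- ref$bases[500]
    alt500 <- setdiff(c("A", "G"), b500)
    alt500 <- if (length(alt500) == 0L || !b500 %in% c("A", "G")) "R" else
      .AMBIG_CODE[paste0(b500, alt500[1])]
    ambig <- data.frame(position = 500L, ref = b500,
                        alt = unname(alt500), kind = "substitution",
                        stringsAsFactors = FALSE)

    grid <- expand.grid(gender = c("male", "female"),
                        age_group = 1:4,
                        immune = c("severe", "mild"),
                        rep = 1:5, stringsAsFactors = FALSE)
    age_lo <- c(17, 30, 45, 60)
    strata_meta <- data.frame(
      id = sprintf("S%03d", seq_len(nrow(grid))),
      gender = grid$gender,
      age = age_lo[grid$age_group] + grid$rep,
      ethnicity = "Han",
      transmission = "heterosexual",
      cd4_pre = ifelse(grid$immune == "severe", 100 + 10 * grid$rep,
                       250 + 10 * grid$rep),
      stringsAsFactors = FALSE
    )

    null_cfg <- sim_config(n_participants = 300L, n_substitutions = 40L,
                           n_indels = 0L, seed = 101L)
    planted_panel <- sim_variant_panel(ref, 30L, 0L, seed = 7L)
    planted_panel$frequency[1] <- 0.10
    planted_panel$effect[1] <- -55
    planted_cfg <- sim_config(n_participants = 724L,
                              variants = planted_panel, seed = 103L)

    list(
      identity_genome = ref$sequence,
      single_substitution = list(
        genome = apply_variants(ref, single), variants = single),
      indel_genome = list(genome = apply_variants(ref, indel),
                          variants = indel),
      ambiguity_genome = list(genome = apply_variants(ref, ambig),
                              variants = ambig),
      strata_cohort = complete_metadata(strata_meta),
      null_cohort_config = null_cfg,
      planted_cohort_config = planted_cfg
    )
  })
}
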