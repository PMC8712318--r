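# Mutational characterization metrics.

# A small hand-checkable cohort on the bundled reference: variants in
# RNR1 (1005), ND2 (4491), D-loop (93) and an indel in RNR2 (2500).
toy_cohort <- function() {
  ref <- test_ref()
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  v <- function(p) list(position = p, ref = ref$bases[p],
                        alt = unname(transition[ref$bases[p]]),
                        kind = "substitution")
  rows <- list(
    c(list(sample_id = "s1"), v(1005L)),
    c(list(sample_id = "s1"), v(4491L)),
    c(list(sample_id = "s2"), v(1005L)),
    c(list(sample_id = "s2"), v(93L)),
    list(sample_id = "s2", position = 2500L, ref = ref$bases[2500L],
         alt = "-", kind = "deletion")
  )
  df <- do.call(rbind, lapply(rows, as.data.frame))
  toy_calls(df, ref, samples = c("s1", "s2", "s3"))
}

test_that("diversity counts distinct types and volume counts carriers", {
  x <- toy_cohort()
  dv <- diversity_and_volume(x, "gene")
  expect_identical(dv$diversity[dv$unit == "RNR1"], 1L)
  expect_identical(dv$volume[dv$unit == "RNR1"], 2L)  # shared by s1, s2
  expect_identical(dv$diversity[dv$unit == "D-loop"], 1L)
  expect_identical(dv$diversity[dv$unit == "RNR2"], 1L)
  expect_identical(dv$diversity_indel[dv$unit == "RNR2"], 1L)
  genome <- diversity_and_volume(x, "genome")
  expect_identical(genome$diversity, 4L)
  expect_identical(genome$volume, 5L)
})

test_that("individual-scale diversity equals volume", {
  x <- toy_cohort()
  for (s in c("s1", "s2")) {
    dv <- diversity_and_volume(x, "genome", samples = s)
    expect_identical(dv$diversity, dv$volume)
  }
})

test_that("diversity density is diversity per sample per kilobase", {
  expect_identical(diversity_density(10, 5, 2), 1)
  expect_identical(diversity_density(0, 5, 2), 0)
  expect_error(diversity_density(10, 0, 2), "positive")
  x <- toy_cohort()
  ref <- test_ref()
  dd <- diversity_density_table(x, ref, "macrodivision")
  # independent recomputation: RNRs = 2 types (sub + indel) over 3
  # samples and the summed RNR1+RNR2 length in kb
  rnr_kb <- sum(c(1601 - 648 + 1, 3229 - 1671 + 1)) / 1000
  expect_equal(dd$diversity_density[dd$unit == "RNRs"], 2 / 3 / rnr_kb)
})

test_that("relative diversity is observed over possible with guards", {
  expect_equal(round(relative_diversity(1075, 8291), 4), 0.1297)
  expect_equal(relative_diversity(0, 100), 0)
  expect_error(relative_diversity(101, 100), "exceeds")
  x <- toy_cohort()
  sp <- test_space()
  rd <- relative_diversity_table(x, sp)
  nd2 <- rd[rd$gene == "ND2", ]
  expect_identical(nd2$observed_all, 1L)
  expect_true(nd2$relative_all > 0 && nd2$relative_all < 1)
  expect_true(all(rd$relative_all >= 0 & rd$relative_all <= 1))
})

test_that("relative diversity depends only on distinct types", {
  x <- toy_cohort()
  sp <- test_space()
  rd1 <- relative_diversity_table(x, sp)
  # duplicate every participant's calls under new ids
  dup <- x$calls
  dup$sample_id <- paste0(dup$sample_id, "_dup")
  x2 <- mitocohort:::build_calls(rbind(x$calls, dup), test_ref(),
                                 samples = c(x$samples,
                                             paste0(x$samples, "_dup")))
  rd2 <- relative_diversity_table(x2, sp)
  expect_equal(rd1$relative_synonymous, rd2$relative_synonymous)
  expect_equal(rd1$relative_all, rd2$relative_all)
})

test_that("momentum recovers exact linear relationships", {
  sp <- test_space()
  poss <- stats::setNames(sp$per_gene$possible_synonymous,
                          sp$per_gene$gene)
  n <- 50
  obs <- poss * 0.002 * n  # observed/n = 0.002 * possible, exactly
  m <- momentum(obs, n, sp, "synonymous")
  expect_equal(m$beta, 0.002)
  expect_equal(m$r_squared, 1)
  m0 <- momentum(poss * 0, n, sp, "synonymous")
  expect_equal(m0$beta, 0)
  # closed-form check on a toy relation with noise-free intercept
  obs2 <- 5 + poss * 0.001 * n
  m2 <- momentum(obs2, n, sp, "synonymous")
  xv <- as.numeric(poss); yv <- as.numeric(obs2) / n
  expect_equal(m2$beta, sum((xv - mean(xv)) * (yv - mean(yv))) /
                 sum((xv - mean(xv))^2))
  # invariant to gene ordering
  perm <- sample(length(obs))
  m3 <- momentum(obs[perm], n, sp, "synonymous")
  expect_equal(m3$beta, m$beta)
  expect_error(momentum(obs[1:2], n, sp, "synonymous"), ">= 3")
})

test_that("amino-acid change matrix, bias and physicochemical summaries", {
  ref <- test_ref()
  sp <- test_space()
  # find a definite nonsynonymous substitution with a Thr->Ala change
  ct <- mitocohort:::coding_table(ref, "ND5")
  codons <- vapply(split(ct$base, ct$codon_index), paste, character(1),
                   collapse = "")
  tidx <- which(codons %in% c("ACT", "ACC", "ACA", "ACG"))[1]  # Thr codon
  expect_false(is.na(tidx))
  prow <- ct[ct$codon_index == tidx & ct$codon_pos == 1L, ]
  df <- data.frame(sample_id = "s1", position = prow$genomic_pos,
                   ref = prow$base, alt = "G", kind = "substitution",
                   stringsAsFactors = FALSE)  # ACx -> GCx : Thr -> Ala
  x <- toy_calls(df, ref, samples = "s1")
  aam <- amino_acid_changes(x, sp)
  expect_identical(sum(aam$matrix), 1)
  expect_identical(aam$matrix["T", "A"], 1)
  expect_equal(aam$bias[["A"]], 1 / sp$aa_max[["A"]])
  expect_equal(aam$bias_density[["A"]], aam$bias[["A"]] / 1)
  pc <- physicochemical_changes(aam, "acidity_polarity")
  expect_equal(sum(pc$percent), 100)
  expect_equal(pc$count[pc$from_class == "neutral_polar" &
                          pc$to_class == "neutral_apolar"], 1)
  expect_error(physicochemical_changes(aam, "no-such-scheme"), "unknown")
})

test_that("physicochemical prevalences reproduce the published arithmetic", {
  # a matrix with 117 of 460 changes in one class pair prints 25.4%
  aam <- structure(list(
    matrix = matrix(0, 20, 20,
                    dimnames = list(mitocohort:::.AA20,
                                    mitocohort:::.AA20)),
    n_samples = 1), class = "aa_change_matrix")
  aam$matrix["A", "T"] <- 117   # neutral apolar -> neutral polar
  aam$matrix["D", "E"] <- 460 - 117
  pc <- physicochemical_changes(aam, "acidity_polarity")
  got <- pc$percent[pc$from_class == "neutral_apolar" &
                      pc$to_class == "neutral_polar"]
  expect_equal(round(got, 1), 25.4)
  expect_equal(sum(pc$percent), 100, tolerance = 1e-9)
})

test_that("class diversities never exceed total substitution diversity", {
  x <- toy_cohort()
  dv <- diversity_and_volume(x, "gene")
  expect_true(all(dv$diversity_synonymous + dv$diversity_nonsynonymous <=
                    dv$diversity))
})

test_that("momentum_from_calls and the variant-table export round out the surface", {
  x <- toy_cohort()
  sp <- test_space()
  # too few protein genes with observations in the toy cohort -> error
  expect_error(momentum_from_calls(x, sp, "synonymous"), ">= 3")
  path <- tempfile(fileext = ".tsv")
  tab <- write_variant_table(x, path)
  expect_true(file.exists(path))
  back <- utils::read.delim(path)
  expect_identical(nrow(back), nrow(x$calls))
  expect_true(all(c("gene", "macrodivision", "synonymy", "ts_tv",
                    "definite") %in% names(back)))
  expect_identical(back$gene[back$m_notation == "m.93A>G" |
                               back$position == 93], "D-loop")
})
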