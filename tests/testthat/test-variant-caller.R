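# Alignment-based variant calling and annotation.

test_that("aligning the reference to itself yields no variants", {
  ref <- test_ref()
  al <- global_align(ref$sequence, ref)
  expect_identical(al$aligned_query, al$aligned_ref)
  expect_identical(nrow(extract_variants(al)), 0L)
})

test_that("planted substitutions are recovered at coordinates from the scan", {
  ref <- test_ref()
  # positions of two reported substitutions; alt = transition of the
  # bundled base so the plant is valid on the synthetic sequence
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  planted <- data.frame(
    position = c(1005L, 4491L),
    ref = ref$bases[c(1005L, 4491L)],
    alt = unname(transition[ref$bases[c(1005L, 4491L)]]),
    kind = "substitution", stringsAsFactors = FALSE)
  genome <- apply_variants(ref, planted)
  for (engine in c("banded", "needle")) {
    v <- extract_variants(global_align(genome, ref, engine = engine))
    expect_identical(v$position, planted$position)
    expect_identical(v$ref, planted$ref)
    expect_identical(v$alt, planted$alt)
  }
})

test_that("a planted 2-base deletion yields one deletion event", {
  ref <- test_ref()
  del <- data.frame(position = 6000L,
                    ref = paste(ref$bases[6000:6001], collapse = ""),
                    alt = "-", kind = "deletion", stringsAsFactors = FALSE)
  genome <- apply_variants(ref, del)
  v <- extract_variants(global_align(genome, ref))
  expect_identical(nrow(v), 1L)
  expect_identical(v$kind, "deletion")
  expect_identical(nchar(v$ref), 2L)
})

test_that("IUPAC mixture calls are preserved and flagged non-definite", {
  ref <- test_ref()
  pos <- match("A", ref$bases)  # first reference A
  genome <- ref$sequence
  substr(genome, pos, pos) <- "R"
  v <- extract_variants(global_align(genome, ref))
  expect_identical(v$alt, "R")
  ann <- annotate_registry(
    data.frame(m_notation = v$m_notation, position = v$position,
               ref = v$ref, alt = v$alt, kind = v$kind),
    ref)
  expect_false(ann$registry$definite)
  expect_true(is.na(ann$registry$transition))
})

test_that("homopolymer indels are left-aligned to the lowest coordinate", {
  # reference ...ACCCCG...; deleting any C must report the first C
  ref <- toy_ref(c(G1 = "ATGACCCCGGGGTAA"))
  run_start <- as.integer(regexpr("CCCC", ref$sequence))
  chars <- strsplit(ref$sequence, "")[[1]]
  genome <- paste(chars[-(run_start + 3L)], collapse = "")  # delete last C
  v <- extract_variants(global_align(genome, ref, fragment = TRUE))
  expect_identical(v$kind, "deletion")
  expect_identical(v$position, run_start)
  expect_identical(v$ref, "C")
})

test_that("apply-then-call recovers random planted variant sets exactly", {
  ref <- test_ref()
  set.seed(101)
  bases4 <- c("A", "C", "G", "T")
  n_cases <- 40  # scaled for runtime; the acceptance suite runs 100
  for (case in seq_len(n_cases)) {
    n_sub <- sample(1:6, 1)
    pos <- sort(sample(setdiff(200:16000, 3100:3114), n_sub + 1L))
    while (min(diff(pos)) < 10L) {
      pos <- sort(sample(setdiff(200:16000, 3100:3114), n_sub + 1L))
    }
    subs <- data.frame(
      position = pos[seq_len(n_sub)],
      ref = ref$bases[pos[seq_len(n_sub)]],
      alt = vapply(pos[seq_len(n_sub)],
                   function(p) sample(setdiff(bases4, ref$bases[p]), 1),
                   character(1)),
      kind = "substitution", stringsAsFactors = FALSE)
    ip <- pos[n_sub + 1L]
    indel <- if (stats::runif(1) < 0.5) {
      L <- sample(1:3, 1)
      data.frame(position = ip,
                 ref = paste(ref$bases[ip:(ip + L - 1L)], collapse = ""),
                 alt = "-", kind = "deletion", stringsAsFactors = FALSE)
    } else {
      data.frame(position = ip, ref = "-",
                 alt = paste(sample(bases4, 2, replace = TRUE),
                             collapse = ""),
                 kind = "insertion", stringsAsFactors = FALSE)
    }
    # keep only indels already in left-aligned canonical form
    norm <- mitocohort:::normalize_indel(
      indel$position, if (indel$kind == "deletion") indel$ref else indel$alt,
      indel$kind, ref$bases)
    planted <- if (norm$pos == indel$position) rbind(subs, indel) else subs
    planted <- planted[order(planted$position), ]

    called <- extract_variants(global_align(apply_variants(ref, planted),
                                            ref))
    expect_identical(called$position, planted$position)
    expect_identical(called$ref, planted$ref)
    expect_identical(called$alt, planted$alt)
    expect_identical(called$kind, planted$kind)
    # every called substitution's ref base matches the reference
    subs_called <- called[called$kind == "substitution", ]
    expect_identical(subs_called$ref, ref$bases[subs_called$position])
  }
})

test_that("banded and needle engines agree on a multi-variant genome", {
  ref <- test_ref()
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  planted <- data.frame(
    position = c(2500L, 7000L, 12000L),
    ref = ref$bases[c(2500L, 7000L, 12000L)],
    alt = unname(transition[ref$bases[c(2500L, 7000L, 12000L)]]),
    kind = "substitution", stringsAsFactors = FALSE)
  genome <- apply_variants(ref, planted)
  vb <- extract_variants(global_align(genome, ref, engine = "banded"))
  vn <- extract_variants(global_align(genome, ref, engine = "needle"))
  expect_identical(vb[, c("position", "ref", "alt", "kind")],
                   vn[, c("position", "ref", "alt", "kind")])
})

test_that("call_cohort builds a registry with correct carrier counts", {
  ref <- test_ref()
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  mk_sub <- function(p) data.frame(
    position = p, ref = ref$bases[p], alt = unname(transition[ref$bases[p]]),
    kind = "substitution", stringsAsFactors = FALSE)
  shared <- mk_sub(1005L)
  s1 <- rbind(shared, mk_sub(4491L))
  s2 <- shared
  seqs <- c(p1 = apply_variants(ref, s1), p2 = apply_variants(ref, s2),
            p3 = ref$sequence)
  calls <- call_cohort(seqs, ref)
  expect_identical(calls$n_samples, 3L)
  expect_identical(nrow(calls$registry), 2L)
  expect_identical(
    calls$registry$n_carriers[calls$registry$position == 1005L], 2L)
  expect_identical(
    calls$registry$n_carriers[calls$registry$position == 4491L], 1L)
  expect_identical(sum(calls$calls$sample_id == "p3"), 0L)

  expect_error(call_cohort(character(0), ref), "empty")
  expect_error(call_cohort(c(a = ref$sequence, a = ref$sequence), ref),
               "duplicate")
})

test_that("worked annotation examples resolve as published", {
  ref <- test_ref()
  # m.14308T>C: third codon position of light-strand ND6; a transition
  # there is synonymous under the mitochondrial code
  expect_identical(ref$bases[14308], "T")
  a1 <- annotate_variant(list(position = 14308, ref = "T", alt = "C",
                              kind = "substitution"), ref)
  expect_identical(a1$genes$gene, "ND6")
  expect_identical(a1$genes$synonymy, "synonymous")
  expect_true(a1$transition)
  # m.93A>G: control region, not protein-coding
  a2 <- annotate_variant(list(position = 93, ref = ref$bases[93],
                              alt = "G", kind = "substitution"), ref)
  expect_identical(a2$genes$gene, "D-loop")
  expect_identical(a2$genes$synonymy, "not-protein")
  # m.1005T>C: RNR1
  a3 <- annotate_variant(list(position = 1005, ref = ref$bases[1005],
                              alt = "C", kind = "substitution"), ref)
  expect_identical(a3$genes$gene, "RNR1")
  # any A>C substitution is a transversion
  a4 <- annotate_variant(list(position = 93, ref = "A", alt = "C",
                              kind = "substitution"), ref)
  expect_false(a4$transition)
  expect_true(a4$definite)
})

test_that("query validation rejects bad input", {
  ref <- test_ref()
  expect_error(global_align("", ref), "empty")
  expect_error(global_align("ACGTZZZ", ref, fragment = TRUE),
               "non-nucleotide")
  expect_error(global_align(strrep("A", 100), ref), "fragment")
})
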