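# Shared fixtures and independent oracles for the test suite.

# Memoised bundled reference (synthetic sequence, real annotation).
.test_env <- new.env(parent = emptyenv())
test_ref <- function() {
  if (is.null(.test_env$ref)) .test_env$ref <- synthetic_reference()
  .test_env$ref
}
test_space <- function() {
  if (is.null(.test_env$space)) {
    .test_env$space <- enumerate_substitution_space(test_ref())
  }
  .test_env$space
}

# Toy genome: protein genes embedded in short flanks. cds is a named
# character vector of coding sequences (heavy-strand orientation as
# written, reverse-complemented into the genome for light-strand genes).
toy_ref <- function(cds, strand = stats::setNames(rep("heavy", length(cds)),
                                                  names(cds)),
                    incomplete_stop = stats::setNames(
                      rep(0L, length(cds)), names(cds))) {
  flank <- "ACGTACGTAC"
  seqs <- character(0)
  feats <- list()
  pos <- nchar(flank)
  seqs <- flank
  for (g in names(cds)) {
    genomic <- if (strand[[g]] == "light") {
      paste(rev(unname(c(A = "T", C = "G", G = "C", T = "A")[
        strsplit(cds[[g]], "")[[1]]])), collapse = "")
    } else cds[[g]]
    feats[[g]] <- data.frame(
      gene = g, start = pos + 1L, end = pos + nchar(genomic),
      strand = strand[[g]], kind = "protein",
      incomplete_stop = incomplete_stop[[g]], macrodivision = "NDs",
      stringsAsFactors = FALSE
    )
    seqs <- c(seqs, genomic, flank)
    pos <- pos + nchar(genomic) + nchar(flank)
  }
  new_mito_reference(paste(seqs, collapse = ""), do.call(rbind, feats))
}

# Independent brute-force substitution-space oracle: reconstruct each
# gene's coding sequence with Biostrings, mutate every base to every
# alternative and re-translate whole codons under Biostrings' own
# vertebrate-mitochondrial code table.
brute_force_space <- function(ref, incomplete_stop = "polyA") {
  code <- Biostrings::getGeneticCode("2")
  f <- ref$features[ref$features$kind == "protein", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(f))) {
    seg <- substr(ref$sequence, f$start[i], f$end[i])
    if (f$strand[i] == "light") {
      seg <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seg)))
    }
    inc <- f$incomplete_stop[i]
    if (inc > 0L) {
      if (incomplete_stop == "polyA") {
        seg <- paste0(seg, strrep("A", 3L - inc))
      } else {
        seg <- substr(seg, 1L, nchar(seg) - inc)
      }
    }
    ncod <- nchar(seg) %/% 3L
    syn <- 0L; nonsyn <- 0L; npos <- 0L
    genomic_len <- f$end[i] - f$start[i] + 1L
    for (k in seq_len(nchar(seg))) {
      if (inc > 0L && incomplete_stop == "polyA" && k > genomic_len) next
      b <- substr(seg, k, k)
      if (!b %in% c("A", "C", "G", "T")) next
      ci <- (k - 1L) %/% 3L + 1L
      codon <- substr(seg, 3L * ci - 2L, 3L * ci)
      if (grepl("[^ACGT]", codon)) next
      npos <- npos + 1L
      for (alt in setdiff(c("A", "C", "G", "T"), b)) {
        mut <- codon
        substr(mut, k - 3L * (ci - 1L), k - 3L * (ci - 1L)) <- alt
        if (code[[codon]] == code[[mut]]) syn <- syn + 1L else
          nonsyn <- nonsyn + 1L
      }
    }
    out[[f$gene[i]]] <- c(synonymous = syn, nonsynonymous = nonsyn,
                          positions = npos)
  }
  out
}

# Random sense-codon coding sequence of n codons (valid ORF not
# required by the enumeration, but keep start/stop realistic).
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "AGA", "AGG")
  codons <- names(Biostrings::getGeneticCode("2"))
  sense <- setdiff(codons, stops)
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

# Hand-rolled calls object from a long table of per-sample variants.
toy_calls <- function(df, ref, samples = unique(df$sample_id)) {
  df$m_notation <- mapply(mitocohort:::m_notation, df$position, df$ref,
                          df$alt, df$kind, USE.NAMES = FALSE)
  df <- df[, c("sample_id", "m_notation", "position", "ref", "alt", "kind")]
  mitocohort:::build_calls(df, ref, samples = samples)
}
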