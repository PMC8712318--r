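# Global pairwise alignment of cohort genomes against the reference and
# extraction of substitutions / indels in m.-notation.

#' Globally align a query sequence to the mitochondrial reference
#'
#' Two engines are available. `"needle"` is the classical full
#' Needleman-Wunsch global alignment as implemented by
#' [Biostrings::pairwiseAlignment()] with EMBOSS-default DNA scoring
#' (match 5, mismatch -4, gap open 10, gap extend 0.5). `"banded"`
#' (default) is a compiled banded global aligner with the same scoring
#' that exploits the near-identity of cohort mitochondrial genomes to
#' the reference; it is two orders of magnitude faster and is
#' cross-checked against the needle engine in the test suite. Both are
#' deterministic under fixed penalties and tie-break rules.
#'
#' @param query Nucleotide string (IUPAC ambiguity codes permitted).
#' @param ref A `mito_reference`, or a plain nucleotide string.
#' @param gap_open,gap_extend Affine gap penalties.
#' @param engine `"banded"` or `"needle"`.
#' @param band Half-width of the banded engine's diagonal band
#'   (default adapts to the length difference).
#' @param fragment If `TRUE`, skip the whole-genome length sanity check
#'   (15,000-18,000 bp) so partial fragments can be aligned.
#' @return Object of class `mito_alignment`: list with `aligned_query`,
#'   `aligned_ref` (equal-length gapped strings), `score`, `engine`.
#' @export
global_align <- function(query, ref, gap_open = 10, gap_extend = 0.5,
                         engine = c("banded", "needle"), band = NULL,
                         fragment = FALSE) {
  engine <- match.arg(engine)
  refseq <- if (inherits(ref, "mito_reference")) ref$sequence else
    toupper(as.character(ref))
  query <- toupper(as.character(query))
  if (nchar(query) == 0L) stop("query sequence is empty")
  qchars <- strsplit(query, "", fixed = TRUE)[[1]]
  if (!all(qchars %in% names(.IUPAC_SETS))) {
    stop("query contains non-nucleotide characters")
  }
  if (!fragment && (nchar(query) < 15000L || nchar(query) > 18000L)) {
    stop("query length ", nchar(query), " outside the whole-genome band ",
         "15,000-18,000; use fragment = TRUE for partial sequences")
  }

  if (engine == "banded") {
    if (is.null(band)) {
      band <- max(64L, 2L * abs(nchar(query) - nchar(refseq)) + 32L)
    }
    res <- banded_align_cpp(query, refseq, 5, -4, 1, gap_open, gap_extend,
                            as.integer(band))
    out <- list(aligned_query = res$aligned_query,
                aligned_ref = res$aligned_ref,
                score = res$score, engine = "banded")
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                    baseOnly = FALSE)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(refseq),
      type = if (fragment) "overlap" else "global",
      substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend
    )
    out <- list(
      aligned_query = as.character(Biostrings::alignedPattern(al)),
      aligned_ref = as.character(Biostrings::alignedSubject(al)),
      score = Biostrings::score(al), engine = "needle"
    )
  }
  if (nchar(out$aligned_query) != nchar(out$aligned_ref)) {
    stop("internal error: gapped strings of unequal length")
  }
  class(out) <- "mito_alignment"
  out
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat("<mito_alignment> ", nchar(x$aligned_ref), " columns, engine ",
      x$engine, ", score ", format(x$score), "\n", sep = "")
  invisible(x)
}

# Left-align an indel against the reference: shift the event towards
# lower coordinates while the flanking reference base equals the last
# base of the (rotated) indel sequence. `pos` is the first deleted base
# for deletions, or the reference base preceding the insertion point for
# insertions.
normalize_indel <- function(pos, seq, kind, ref_chars) {
  L <- nchar(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (kind == "deletion") {
    while (pos > 1L && ref_chars[pos - 1L] == s[L]) {
      s <- c(ref_chars[pos - 1L], s[-L])
      pos <- pos - 1L
    }
  } else {
    while (pos > 0L && ref_chars[pos] == s[L]) {
      s <- c(s[L], s[-L])
      pos <- pos - 1L
    }
  }
  list(pos = pos, seq = paste(s, collapse = ""))
}

m_notation <- function(position, ref, alt, kind) {
  if (kind == "substitution") {
    sprintf("m.%d%s>%s", position, ref, alt)
  } else if (kind == "deletion") {
    if (nchar(ref) == 1L) sprintf("m.%ddel%s", position, ref)
    else sprintf("m.%d_%ddel%s", position, position + nchar(ref) - 1L, ref)
  } else {
    sprintf("m.%d_%dins%s", position, position + 1L, alt)
  }
}

#' Extract variants from a global alignment
#'
#' Walks the alignment columns, mapping each back to a reference
#' coordinate. Mismatch columns yield substitutions (IUPAC ambiguity
#' codes in the query are preserved in `alt`); runs of gaps are
#' collapsed into single insertion/deletion events and left-aligned
#' against the reference, so homopolymer indels are reported at the
#' lowest coordinate. Query `N` calls and columns over the reference `N`
#' placeholder are treated as no-calls, not variants.
#'
#' @param alignment A `mito_alignment`.
#' @return Data frame with columns `position`, `ref`, `alt`, `kind` and
#'   `m_notation`. Deletions carry the deleted reference bases in `ref`
#'   and `alt = "-"`; insertions carry `ref = "-"`, the inserted bases
#'   in `alt`, and `position` = the reference base preceding the
#'   insertion point.
#' @export
extract_variants <- function(alignment) {
  aq <- strsplit(alignment$aligned_query, "", fixed = TRUE)[[1]]
  ar <- strsplit(alignment$aligned_ref, "", fixed = TRUE)[[1]]
  n <- length(ar)
  ref_chars <- ar[ar != "-"]

  out <- list()
  k <- 0L
  refpos <- 0L
  i <- 1L
  while (i <= n) {
    if (ar[i] != "-" && aq[i] != "-") {
      refpos <- refpos + 1L
      if (aq[i] != ar[i] && aq[i] != "N" && ar[i] != "N") {
        k <- k + 1L
        out[[k]] <- data.frame(position = refpos, ref = ar[i], alt = aq[i],
                               kind = "substitution",
                               stringsAsFactors = FALSE)
      }
      i <- i + 1L
    } else if (aq[i] == "-") {
      # deletion run (gap in query)
      j <- i
      while (j <= n && aq[j] == "-") j <- j + 1L
      delseq <- paste(ar[i:(j - 1L)], collapse = "")
      start <- refpos + 1L
      refpos <- refpos + (j - i)
      norm <- normalize_indel(start, delseq, "deletion", ref_chars)
      k <- k + 1L
      out[[k]] <- data.frame(position = norm$pos, ref = norm$seq, alt = "-",
                             kind = "deletion", stringsAsFactors = FALSE)
      i <- j
    } else {
      # insertion run (gap in reference)
      j <- i
      while (j <= n && ar[j] == "-") j <- j + 1L
      insseq <- paste(aq[i:(j - 1L)], collapse = "")
      norm <- normalize_indel(refpos, insseq, "insertion", ref_chars)
      k <- k + 1L
      out[[k]] <- data.frame(position = norm$pos, ref = "-", alt = norm$seq,
                             kind = "insertion", stringsAsFactors = FALSE)
      i <- j
    }
  }
  if (k == 0L) {
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), kind = character(),
                      m_notation = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$kind), , drop = FALSE]
  res$m_notation <- mapply(m_notation, res$position, res$ref, res$alt,
                           res$kind, USE.NAMES = FALSE)
  rownames(res) <- NULL
  res
}

#' Apply a set of variants to a reference sequence
#'
#' Inverse of variant calling: plants substitutions, deletions and
#' insertions (columns `position`, `ref`, `alt`, `kind`) into a
#' reference sequence, validating that `ref` matches the reference at
#' `position`. Used by the synthetic-cohort generator and by round-trip
#' tests.
#'
#' @param ref A `mito_reference` or nucleotide string.
#' @param variants Data frame of variants as returned by
#'   [extract_variants()].
#' @return The mutated nucleotide string.
#' @export
apply_variants <- function(ref, variants) {
  seqstr <- if (inherits(ref, "mito_reference")) ref$sequence else
    toupper(as.character(ref))
  if (nrow(variants) == 0L) return(seqstr)
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  v <- variants[order(-variants$position), , drop = FALSE]
  pieces <- as.list(chars)
  for (i in seq_len(nrow(v))) {
    pos <- v$position[i]
    kind <- v$kind[i]
    if (kind == "substitution") {
      if (chars[pos] != v$ref[i]) {
        stop("variant ref mismatch at position ", pos, ": reference has ",
             chars[pos], ", variant says ", v$ref[i])
      }
      pieces[[pos]] <- v$alt[i]
    } else if (kind == "deletion") {
      L <- nchar(v$ref[i])
      have <- paste(chars[pos:(pos + L - 1L)], collapse = "")
      if (have != v$ref[i]) {
        stop("deletion ref mismatch at position ", pos)
      }
      for (p in pos:(pos + L - 1L)) pieces[[p]] <- ""
    } else {
      # insertion after `pos` (pos may be 0 for an insertion before base 1)
      if (pos == 0L) {
        pieces[[1L]] <- paste0(v$alt[i], pieces[[1L]])
      } else {
        pieces[[pos]] <- paste0(pieces[[pos]], v$alt[i])
      }
    }
  }
  paste(unlist(pieces), collapse = "")
}

#' Call variants for every participant in a multi-FASTA
#'
#' Aligns each record to the reference, extracts and annotates variants,
#' and assembles a cohort-level registry of distinct variant types with
#' per-type carrier counts.
#'
#' @param fasta Path to a multi-record FASTA, or a named character
#'   vector / `Biostrings::DNAStringSet` of sequences.
#' @param ref A `mito_reference`.
#' @param engine,gap_open,gap_extend,band Passed to [global_align()].
#' @param fragment Allow non-genome-length records.
#' @param verbose Print a per-sequence alignment summary line.
#' @return Object of class `mito_calls`: list with `calls` (long data
#'   frame: one row per sample x variant), `registry` (distinct variant
#'   types with `n_carriers` and annotation flags, see
#'   [annotate_registry()]), `gene_annotations` (per type x gene
#'   synonymy), `samples` and `n_samples`.
#' @export
call_cohort <- function(fasta, ref, engine = c("banded", "needle"),
                        gap_open = 10, gap_extend = 0.5, band = NULL,
                        fragment = FALSE, verbose = FALSE) {
  engine <- match.arg(engine)
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    seqs <- stats::setNames(as.character(seqs),
                            sub("\\s.*$", "", names(seqs)))
  } else if (inherits(fasta, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(fasta), names(fasta))
  } else {
    seqs <- fasta
  }
  if (length(seqs) == 0L) stop("no sequences to call (empty FASTA)")
  ids <- names(seqs)
  if (is.null(ids) || any(ids == "")) stop("all records must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  per_sample <- vector("list", length(seqs))
  for (s in seq_along(seqs)) {
    al <- global_align(seqs[[s]], ref, gap_open = gap_open,
                       gap_extend = gap_extend, engine = engine,
                       band = band, fragment = fragment)
    v <- extract_variants(al)
    if (verbose) {
      message(sprintf("%s: %d variants (score %.1f)", ids[s], nrow(v),
                      al$score))
    }
    if (nrow(v) > 0L) v$sample_id <- ids[s]
    per_sample[[s]] <- v
  }
  nonempty <- per_sample[vapply(per_sample, nrow, 1L) > 0L]
  if (length(nonempty) > 0L) {
    calls <- do.call(rbind, nonempty)
    calls <- calls[, c("sample_id", "m_notation", "position", "ref", "alt",
                       "kind")]
    rownames(calls) <- NULL
  } else {
    calls <- data.frame(sample_id = character(), m_notation = character(),
                        position = integer(), ref = character(),
                        alt = character(), kind = character(),
                        stringsAsFactors = FALSE)
  }
  build_calls(calls, ref, samples = ids)
}

# Assemble a mito_calls object from a long call table (shared by
# call_cohort and the simulator ledger path).
build_calls <- function(calls, ref, samples) {
  types <- unique(calls[, c("m_notation", "position", "ref", "alt", "kind")])
  if (nrow(types) > 0L) {
    counts <- table(calls$m_notation)
    types$n_carriers <- as.integer(counts[types$m_notation])
    types <- types[order(types$position, types$m_notation), , drop = FALSE]
    rownames(types) <- NULL
  } else {
    types$n_carriers <- integer()
  }
  ann <- annotate_registry(types, ref)
  structure(
    list(calls = calls, registry = ann$registry,
         gene_annotations = ann$gene_annotations,
         samples = samples, n_samples = length(samples)),
    class = "mito_calls"
  )
}

#' @export
print.mito_calls <- function(x, ...) {
  cat("<mito_calls> ", x$n_samples, " samples, ", nrow(x$registry),
      " distinct variant types, ", nrow(x$calls), " calls\n", sep = "")
  invisible(x)
}

#' Export a cohort variant table
#'
#' Writes the per-sample calls joined with type-level annotation as
#' tab-delimited text (columns sample_id, m_notation, position, ref,
#' alt, kind, gene, macrodivision, synonymy, ts_tv, definite).
#'
#' @param x A `mito_calls` object.
#' @param path Output path.
#' @return The exported data frame, invisibly.
#' @export
write_variant_table <- function(x, path) {
  ga <- x$gene_annotations
  gene_by_type <- tapply(ga$gene, ga$m_notation,
                         function(g) paste(unique(g), collapse = "/"))
  div_by_type <- tapply(ga$macrodivision, ga$m_notation,
                        function(g) paste(unique(g), collapse = "/"))
  syn_by_type <- tapply(ga$synonymy, ga$m_notation,
                        function(g) paste(unique(g), collapse = "/"))
  reg <- x$registry
  tab <- merge(x$calls, data.frame(
    m_notation = reg$m_notation,
    definite = reg$definite,
    ts_tv = ifelse(is.na(reg$transition), NA,
                   ifelse(reg$transition, "transition", "transversion")),
    stringsAsFactors = FALSE
  ), by = "m_notation", sort = FALSE)
  tab$gene <- unname(gene_by_type[tab$m_notation])
  tab$macrodivision <- unname(div_by_type[tab$m_notation])
  tab$synonymy <- unname(syn_by_type[tab$m_notation])
  tab <- tab[, c("sample_id", "m_notation", "position", "ref", "alt", "kind",
                 "gene", "macrodivision", "synonymy", "ts_tv", "definite")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
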