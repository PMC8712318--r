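# The mitochondrial reference model: sequence, gene features,
# macrodivisions and position-to-region lookup.

.MITO_LENGTH <- 16569L

.MACRODIVISIONS <- c("D-loop", "RNRs", "tRNAs", "NDs", "COs", "ATPs", "CYB")

.MITO_GENES <- c(
  "D-loop", "TRNF", "RNR1", "TRNV", "RNR2", "TRNL1", "ND1", "TRNI", "TRNQ",
  "TRNM", "ND2", "TRNW", "TRNA", "TRNN", "TRNC", "TRNY", "CO1", "TRNS1",
  "TRND", "CO2", "TRNK", "ATP8", "ATP6", "CO3", "TRNG", "ND3", "TRNR",
  "ND4L", "ND4", "TRNH", "TRNS2", "TRNL2", "ND5", "ND6", "TRNE", "CYB",
  "TRNT", "TRNP"
)

#' Construct a mitochondrial reference object
#'
#' Low-level constructor used by [load_reference()] and by tests that
#' build toy genomes. `features` holds one row per feature arc with
#' columns `gene`, `start`, `end` (1-based inclusive), `strand`
#' (`heavy`/`light`), `kind` (`protein`/`tRNA`/`rRNA`/`control`),
#' `incomplete_stop` (0-2 trailing bases completed by polyadenylation)
#' and `macrodivision`. A wrap-around control region is represented as
#' two arcs sharing one gene name.
#'
#' @param sequence Nucleotide string (`A,C,G,T,N`).
#' @param features Feature data frame as described above.
#' @param check_genome If `TRUE`, additionally require the canonical
#'   16,569-bp length and the full 37-gene + control-region annotation.
#' @return An object of class `mito_reference`.
#' @export
new_mito_reference <- function(sequence, features, check_genome = FALSE) {
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("invalid nucleotide characters at positions ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  }

  if (check_genome && n != .MITO_LENGTH) {
    stop("reference length mismatch: expected ", .MITO_LENGTH,
         " bp, got ", n, " bp")
  }

  req <- c("gene", "start", "end", "strand", "kind", "incomplete_stop",
           "macrodivision")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols) > 0L) {
    stop("feature table malformed: missing columns ",
         paste(missing_cols, collapse = ", "))
  }
  features <- features[, req]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$incomplete_stop <- as.integer(features$incomplete_stop)
  if (any(features$start < 1L) || any(features$end > n)) {
    stop("feature table malformed: coordinates outside 1..", n)
  }
  if (any(features$start > features$end)) {
    stop("feature table malformed: start > end in row(s) ",
         paste(which(features$start > features$end), collapse = ", "),
         " (wrap-around regions must be split into two arcs)")
  }
  if (!all(features$strand %in% c("heavy", "light"))) {
    stop("feature table malformed: strand must be 'heavy' or 'light'")
  }
  if (!all(features$kind %in% c("protein", "tRNA", "rRNA", "control"))) {
    stop("feature table malformed: unknown feature kind")
  }
  if (!all(features$macrodivision %in% .MACRODIVISIONS)) {
    stop("feature table malformed: macrodivision must be one of ",
         paste(.MACRODIVISIONS, collapse = ", "))
  }
  prot <- features[features$kind == "protein", , drop = FALSE]
  if (nrow(prot) > 0L) {
    len <- prot$end - prot$start + 1L - prot$incomplete_stop
    off <- which(len %% 3L != 0L)
    if (length(off) > 0L) {
      stop("feature table malformed: protein gene(s) ",
           paste(prot$gene[off], collapse = ", "),
           " have coding length not divisible by 3")
    }
  }

  if (check_genome) {
    missing_genes <- setdiff(.MITO_GENES, features$gene)
    if (length(missing_genes) > 0L) {
      stop("feature table missing gene(s): ",
           paste(missing_genes, collapse = ", "))
    }
  }

  structure(
    list(sequence = sequence, length = n, features = features,
         bases = chars),
    class = "mito_reference"
  )
}

#' Load the mitochondrial reference from FASTA and a feature table
#'
#' Reads a single-record FASTA holding the 16,569-bp mitochondrial
#' reference in rCRS coordinates and a tab-delimited feature table
#' listing the 37 genes plus the control region, and returns a validated
#' [new_mito_reference()] object.
#'
#' @param reference_fasta Path to a FASTA file with exactly one record.
#' @param feature_table Path to a tab-delimited feature table (columns
#'   `gene`, `start`, `end`, `strand`, `kind`, `incomplete_stop`,
#'   `macrodivision`; `#` comment lines allowed).
#' @return A `mito_reference` object.
#' @export
#' @examples
#' ref <- synthetic_reference()
#' ref$length
load_reference <- function(reference_fasta, feature_table) {
  seqs <- Biostrings::readDNAStringSet(reference_fasta)
  if (length(seqs) != 1L) {
    stop("reference FASTA must contain exactly one record, found ",
         length(seqs))
  }
  features <- utils::read.delim(feature_table, stringsAsFactors = FALSE,
                                comment.char = "#")
  new_mito_reference(as.character(seqs[[1]]), features, check_genome = TRUE)
}

#' Bundled synthetic stand-in for the rCRS reference
#'
#' Loads the reference fixture shipped with the package. The gene
#' annotation (coordinates, strands, incomplete stop codons,
#' macrodivisions) is the canonical NC_012920 annotation, but the
#' nucleotide sequence is a SYNTHETIC stand-in generated by
#' [make_synthetic_reference()]: coordinate-dependent behaviour matches
#' the real mitochondrial genome exactly, while sequence-content
#' statistics (e.g. the synonymous/nonsynonymous composition of the
#' substitution space) do not.
#'
#' @return A `mito_reference` object of length 16,569.
#' @export
synthetic_reference <- function() {
  fasta <- system.file("extdata", "synthetic_rCRS.fasta",
                       package = "mitocohort")
  feats <- system.file("extdata", "rCRS_features.tsv",
                       package = "mitocohort")
  if (fasta == "" || feats == "") {
    fasta <- file.path("inst", "extdata", "synthetic_rCRS.fasta")
    feats <- file.path("inst", "extdata", "rCRS_features.tsv")
  }
  load_reference(fasta, feats)
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("<mito_reference> ", x$length, " bp, ",
      length(unique(x$features$gene)), " named features\n", sep = "")
  invisible(x)
}

#' Map a reference position to its gene(s) and macrodivision(s)
#'
#' A position inside overlapping genes (e.g. the ATP8/ATP6 or ND4L/ND4
#' overlaps) returns one row per gene. Control-region positions return
#' the D-loop. Positions covered by no feature return a zero-row data
#' frame (non-coding/intergenic).
#'
#' @param position 1-based reference coordinate (scalar).
#' @param ref A `mito_reference`.
#' @return Data frame with columns `gene`, `macrodivision`, `kind`,
#'   `strand`.
#' @export
#' @examples
#' ref <- synthetic_reference()
#' region_of(1005, ref)   # RNR1 / RNRs
#' region_of(93, ref)     # D-loop
region_of <- function(position, ref) {
  stopifnot(length(position) == 1L)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > ref$length) {
    stop("position must be in 1..", ref$length)
  }
  f <- ref$features
  hit <- f[f$start <= position & position <= f$end, , drop = FALSE]
  out <- unique(hit[, c("gene", "macrodivision", "kind", "strand")])
  rownames(out) <- NULL
  out
}

# Total length of each named feature (arcs summed, overlaps within a
# single gene not expected).
gene_lengths <- function(ref) {
  f <- ref$features
  len <- tapply(f$end - f$start + 1L, f$gene, sum)
  stats::setNames(as.integer(len), names(len))
}

#' Lengths of the seven macrodivisions in base pairs
#'
#' Sum of member-gene lengths per macrodivision (positions inside two
#' genes of the same macrodivision are counted once per gene).
#'
#' @param ref A `mito_reference`.
#' @return Named integer vector over the macrodivisions present.
#' @export
macrodivision_lengths <- function(ref) {
  f <- ref$features
  len <- tapply(f$end - f$start + 1L, f$macrodivision, sum)
  stats::setNames(as.integer(len), names(len))
}

# Per-base coding table of one protein gene: genomic position, codon
# index, position within codon and the coding-strand base. With
# incomplete_stop = "polyA" the trailing partial codon is completed with
# A's (its phantom bases carry genomic_pos = NA).
coding_table <- function(ref, gene, incomplete_stop = c("polyA", "exclude")) {
  incomplete_stop <- match.arg(incomplete_stop)
  f <- ref$features
  row <- f[f$gene == gene & f$kind == "protein", , drop = FALSE]
  if (nrow(row) != 1L) stop("'", gene, "' is not a single-arc protein gene")
  start <- row$start; end <- row$end; inc <- row$incomplete_stop
  if (row$strand == "heavy") {
    pos <- start:end
  } else {
    pos <- end:start
  }
  bases <- ref$bases[pos]
  if (row$strand == "light") bases <- unname(.COMPLEMENT[bases])
  if (inc > 0L) {
    if (incomplete_stop == "polyA") {
      bases <- c(bases, rep("A", 3L - inc))
      pos <- c(pos, rep(NA_integer_, 3L - inc))
    } else {
      keep <- seq_len(length(pos) - inc)
      bases <- bases[keep]
      pos <- pos[keep]
    }
  }
  ncod <- length(pos) %/% 3L
  data.frame(
    genomic_pos = pos,
    codon_index = rep(seq_len(ncod), each = 3L),
    codon_pos = rep(1:3, times = ncod),
    base = bases,
    stringsAsFactors = FALSE
  )
}
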