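# Vertebrate mitochondrial genetic code (NCBI translation table 2) and
# amino-acid physicochemical classifications.

.STANDARD_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# Table 2 differs from the standard code at four codons.
.MITO_CODE <- local({
  code <- .STANDARD_CODE
  code["ATA"] <- "M"   # Ile -> Met
  code["TGA"] <- "W"   # stop -> Trp
  code["AGA"] <- "*"   # Arg -> stop
  code["AGG"] <- "*"   # Arg -> stop
  code
})

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Vertebrate mitochondrial genetic code
#'
#' Returns the codon table of NCBI translation table 2 (vertebrate
#' mitochondrial) together with the amino-acid physicochemical class
#' schemes used by [physicochemical_changes()].
#'
#' Table 2 deviates from the universal code at AGA/AGG (stop instead of
#' Arg), ATA (Met instead of Ile) and TGA (Trp instead of stop).
#'
#' @return An object of class `mito_genetic_code`: a list with elements
#'   `codons` (named character vector of 64 codons to one-letter amino
#'   acids, `"*"` for stop), `stops` (the stop codons) and `classes`
#'   (a data frame of physicochemical class assignments, see
#'   [aa_class_schemes()]).
#' @export
#' @examples
#' code <- mito_genetic_code()
#' code$codons[c("TGA", "ATA", "AGA")]
mito_genetic_code <- function() {
  structure(
    list(
      codons = .MITO_CODE,
      stops = names(.MITO_CODE)[.MITO_CODE == "*"],
      classes = aa_class_schemes()
    ),
    class = "mito_genetic_code"
  )
}

#' Translate a single codon under the vertebrate mitochondrial code
#'
#' @param codon A 3-letter nucleotide string over `A,C,G,T`.
#' @param code A [mito_genetic_code()] object.
#' @return One-letter amino-acid code, `"*"` for a stop codon, or `NA`
#'   when the codon contains an ambiguous or invalid base
#'   (untranslatable).
#' @export
#' @examples
#' translate_codon("TGA")  # "W" (not stop, unlike the universal code)
#' translate_codon("ATA")  # "M"
translate_codon <- function(codon, code = mito_genetic_code()) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L) stop("codon must be a 3-mer, got '", codon, "'")
  aa <- unname(code$codons[codon])
  if (length(aa) == 0L || is.na(aa)) return(NA_character_)
  aa
}

# Vectorised lookup; untranslatable codons map to NA.
translate_codons <- function(codons, code = mito_genetic_code()) {
  aa <- unname(code$codons[codons])
  aa[!(codons %in% names(code$codons))] <- NA_character_
  aa
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", V = "B", D = "H", H = "D")

# Reverse complement of a plain character string (IUPAC-aware).
revcomp <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  paste(rev(unname(.COMPLEMENT[chars])), collapse = "")
}

# IUPAC ambiguity sets (single-base codes excluded from "definite").
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Amino-acid physicochemical class schemes
#'
#' Class partitions of the 20 amino acids used to summarise the
#' physicochemical consequences of amino-acid replacements. The
#' `acidity_polarity` scheme distinguishes neutral apolar, neutral polar,
#' acidic and basic residues; the remaining schemes (hydropathy, volume,
#' chemical, charge, hydrogen donor/acceptor, polarity) follow the IMGT
#' amino-acid classification. The assignments are shipped as a plain-text
#' configuration fixture so that alternative partitions can be swapped in.
#'
#' @return A data frame with columns `scheme`, `class` and `aa`.
#' @export
aa_class_schemes <- function() {
  path <- system.file("extdata", "aa_classes.tsv", package = "mitocohort")
  if (path == "") {  # during development, before installation
    path <- file.path("inst", "extdata", "aa_classes.tsv")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  tab
}

# class of each amino acid under one scheme, as a named vector
aa_classes_for_scheme <- function(scheme, classes = aa_class_schemes()) {
  sub <- classes[classes$scheme == scheme, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("unknown physicochemical scheme '", scheme, "'; available: ",
         paste(unique(classes$scheme), collapse = ", "))
  }
  stats::setNames(sub$class, sub$aa)
}
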