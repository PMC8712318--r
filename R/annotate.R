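# Variant annotation: gene membership, synonymy via codon
# reconstruction, transition/transversion and definiteness.

# Precompute per-protein-gene codon lookup tables.
protein_index <- function(ref, incomplete_stop = "polyA",
                          code = mito_genetic_code()) {
  f <- ref$features
  genes <- f$gene[f$kind == "protein"]
  idx <- list()
  for (g in genes) {
    ct <- coding_table(ref, g, incomplete_stop)
    codons <- vapply(split(ct$base, ct$codon_index),
                     paste, character(1), collapse = "")
    codons <- codons[order(as.integer(names(codons)))]
    idx[[g]] <- list(table = ct, codons = unname(codons),
                     strand = f$strand[f$kind == "protein" & f$gene == g][1])
  }
  idx
}

.is_transition <- function(ref, alt) {
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

#' Annotate a single variant
#'
#' Computes per-gene synonymy by codon reconstruction (light-strand
#' genes are complemented before translation), the
#' transition/transversion flag (defined only for definite
#' substitutions) and the definiteness flag (the observed base is a
#' single specified nucleotide, not an IUPAC mixture code).
#'
#' @param variant A one-row data frame or list with `position`, `ref`,
#'   `alt` and `kind`.
#' @param ref A `mito_reference`.
#' @param code A [mito_genetic_code()].
#' @return A list with `genes` (data frame: gene, macrodivision,
#'   synonymy, codon_number, aa_ref, aa_alt), `transition` (logical or
#'   NA) and `definite` (logical).
#' @export
#' @examples
#' ref <- synthetic_reference()
#' annotate_variant(list(position = 14308, ref = "T", alt = "C",
#'                       kind = "substitution"), ref)
annotate_variant <- function(variant, ref, code = mito_genetic_code()) {
  types <- data.frame(
    m_notation = m_notation(variant$position, variant$ref, variant$alt,
                            variant$kind),
    position = as.integer(variant$position), ref = variant$ref,
    alt = variant$alt, kind = variant$kind, n_carriers = 1L,
    stringsAsFactors = FALSE
  )
  ann <- annotate_registry(types, ref, code)
  list(
    genes = ann$gene_annotations[, c("gene", "macrodivision", "synonymy",
                                     "codon_number", "aa_ref", "aa_alt")],
    transition = ann$registry$transition[1],
    definite = ann$registry$definite[1]
  )
}

#' Annotate a registry of distinct variant types
#'
#' @param types Data frame of distinct variant types (`m_notation`,
#'   `position`, `ref`, `alt`, `kind`, optionally `n_carriers`).
#' @param ref A `mito_reference`.
#' @param code A [mito_genetic_code()].
#' @return A list with `registry` (the input plus `definite`,
#'   `transition`, `n_genes` columns) and `gene_annotations` (one row
#'   per type x overlapping gene: `m_notation`, `position`, `kind`,
#'   `gene`, `macrodivision`, `gene_kind`, `synonymy`, `codon_number`,
#'   `aa_ref`, `aa_alt`). Types covered by no feature get no
#'   gene-annotation rows (non-coding/intergenic).
#' @export
annotate_registry <- function(types, ref, code = mito_genetic_code()) {
  pidx <- protein_index(ref, code = code)

  definite <- types$kind == "substitution" &
    types$alt %in% c("A", "C", "G", "T")
  transition <- ifelse(definite, .is_transition(types$ref, types$alt), NA)

  rows <- list()
  k <- 0L
  n_genes <- integer(nrow(types))
  for (i in seq_len(nrow(types))) {
    pos <- types$position[i]
    if (pos < 1L) next  # insertion before base 1
    regions <- region_of(pos, ref)
    n_genes[i] <- nrow(regions)
    if (nrow(regions) == 0L) next
    for (r in seq_len(nrow(regions))) {
      gene <- regions$gene[r]
      syn <- "not-protein"
      codon_number <- NA_integer_
      aa_ref <- NA_character_
      aa_alt <- NA_character_
      if (regions$kind[r] == "protein" && types$kind[i] == "substitution") {
        gi <- pidx[[gene]]
        j <- match(pos, gi$table$genomic_pos)
        if (is.na(j)) {
          # beyond the classified codons (e.g. "exclude" handling)
          syn <- NA_character_
        } else {
          ci <- gi$table$codon_index[j]
          cp <- gi$table$codon_pos[j]
          codon <- gi$codons[ci]
          aa_ref <- translate_codons(codon, code)
          codon_number <- ci
          if (definite[i]) {
            alt_c <- if (gi$strand == "light")
              unname(.COMPLEMENT[types$alt[i]]) else types$alt[i]
            mut <- codon
            substr(mut, cp, cp) <- alt_c
            aa_alt <- translate_codons(mut, code)
            if (is.na(aa_ref) || is.na(aa_alt)) {
              syn <- NA_character_
            } else {
              syn <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
            }
          } else {
            syn <- NA_character_  # ambiguous or indel: synonymy undefined
          }
        }
      } else if (types$kind[i] != "substitution") {
        syn <- NA_character_
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        m_notation = types$m_notation[i], position = pos,
        kind = types$kind[i], gene = gene,
        macrodivision = regions$macrodivision[r],
        gene_kind = regions$kind[r], synonymy = syn,
        codon_number = codon_number, aa_ref = aa_ref, aa_alt = aa_alt,
        stringsAsFactors = FALSE
      )
    }
  }
  gene_annotations <- if (k > 0L) do.call(rbind, rows) else data.frame(
    m_notation = character(), position = integer(), kind = character(),
    gene = character(), macrodivision = character(), gene_kind = character(),
    synonymy = character(), codon_number = integer(), aa_ref = character(),
    aa_alt = character(), stringsAsFactors = FALSE
  )
  registry <- types
  registry$definite <- definite
  registry$transition <- transition
  registry$n_genes <- n_genes
  list(registry = registry, gene_annotations = gene_annotations)
}
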