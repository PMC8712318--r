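# Enumeration of the complete possible-substitution space over the
# protein-coding mitochondrial genes.

#' Enumerate all possible coding substitutions
#'
#' For every classified position of every protein-coding gene and each of
#' its three alternative bases, the substitution is classified as
#' synonymous or nonsynonymous by codon re-translation under the
#' vertebrate mitochondrial code (light-strand genes are
#' reverse-complemented before translation). Substitutions creating or
#' destroying a stop codon count as nonsynonymous. Positions whose
#' reference codon contains an untranslatable base (the N placeholder)
#' are excluded.
#'
#' Incomplete stop codons (gene-terminal T/TA completed by mRNA
#' polyadenylation) are handled by the `incomplete_stop` switch:
#' `"polyA"` (default) completes the trailing partial codon with A's so
#' its genomic bases are classified like any other, `"exclude"` drops
#' them from the space. Genome-wide totals are sums over genes, so a
#' position inside two overlapping genes contributes to each
#' independently; this per-gene summation together with `"polyA"` is the
#' convention calibrated against the published totals for the real rCRS
#' (3 x 11,395 = 34,185 possible substitutions).
#'
#' @param ref A `mito_reference`.
#' @param incomplete_stop `"polyA"` or `"exclude"`, see above.
#' @param code A [mito_genetic_code()].
#' @return An object of class `substitution_space`: list with
#'   `per_gene` (data frame of per-gene counts: classified positions,
#'   possible synonymous/nonsynonymous/transitions/transversions),
#'   `totals` (named numeric of genome-wide sums), `aa_max` (named
#'   vector over the 20 amino acids: the maximum possible number of
#'   distinct changes to each target amino acid, the bias denominators)
#'   and `by_target_pair` (possible counts per ordered amino-acid pair).
#' @export
#' @examples
#' ref <- synthetic_reference()
#' sp <- enumerate_substitution_space(ref)
#' sp$totals
enumerate_substitution_space <- function(ref,
                                         incomplete_stop = c("polyA", "exclude"),
                                         code = mito_genetic_code()) {
  incomplete_stop <- match.arg(incomplete_stop)
  f <- ref$features
  genes <- f$gene[f$kind == "protein"]
  if (length(genes) == 0L) stop("reference has no protein-coding features")

  bases4 <- c("A", "C", "G", "T")
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")

  per_gene <- vector("list", length(genes))
  pair_counts <- matrix(0L, 21L, 21L,
                        dimnames = list(c(.AA20, "*"), c(.AA20, "*")))

  for (gi in seq_along(genes)) {
    g <- genes[gi]
    ct <- coding_table(ref, g, incomplete_stop)
    ncod <- max(ct$codon_index)
    codons <- vapply(split(ct$base, ct$codon_index),
                     paste, character(1), collapse = "")
    codons <- codons[order(as.integer(names(codons)))]
    aa_ref <- translate_codons(codons, code)

    n_syn <- 0L; n_nonsyn <- 0L; n_classified <- 0L
    n_ts <- 0L; n_tv <- 0L

    for (cpos in 1:3) {
      rows <- ct[ct$codon_pos == cpos, , drop = FALSE]
      # skip phantom polyA bases (not genomic positions)
      genomic <- !is.na(rows$genomic_pos)
      refb <- rows$base
      ok <- genomic & !is.na(aa_ref[rows$codon_index]) & refb %in% bases4
      if (!any(ok)) next
      idx <- which(ok)
      n_classified <- n_classified + length(idx)
      n_ts <- n_ts + length(idx)        # one transition per position
      n_tv <- n_tv + 2L * length(idx)   # two transversions per position
      for (alt in bases4) {
        sel <- idx[refb[idx] != alt]
        if (length(sel) == 0L) next
        mut <- codons[rows$codon_index[sel]]
        substr(mut, cpos, cpos) <- alt
        aa_alt <- translate_codons(mut, code)
        aa_from <- aa_ref[rows$codon_index[sel]]
        syn <- aa_alt == aa_from
        n_syn <- n_syn + sum(syn)
        n_nonsyn <- n_nonsyn + sum(!syn)
        if (any(!syn)) {
          tb <- table(factor(aa_from[!syn], levels = rownames(pair_counts)),
                      factor(aa_alt[!syn], levels = colnames(pair_counts)))
          pair_counts <- pair_counts + tb
        }
      }
    }
    per_gene[[gi]] <- data.frame(
      gene = g,
      n_positions = n_classified,
      possible_synonymous = n_syn,
      possible_nonsynonymous = n_nonsyn,
      possible_transitions = n_ts,
      possible_transversions = n_tv,
      stringsAsFactors = FALSE
    )
  }

  per_gene <- do.call(rbind, per_gene)
  totals <- c(
    possible_synonymous = sum(per_gene$possible_synonymous),
    possible_nonsynonymous = sum(per_gene$possible_nonsynonymous),
    possible_transitions = sum(per_gene$possible_transitions),
    possible_transversions = sum(per_gene$possible_transversions),
    n_positions = sum(per_gene$n_positions)
  )
  # bias denominators: maxima over 20 amino acids (stop targets excluded)
  aa_max <- pair_counts[.AA20, .AA20]
  structure(
    list(
      per_gene = per_gene,
      totals = totals,
      aa_max = colSums(aa_max),
      by_target_pair = aa_max,
      incomplete_stop = incomplete_stop
    ),
    class = "substitution_space"
  )
}

#' @export
print.substitution_space <- function(x, ...) {
  cat("<substitution_space> ", nrow(x$per_gene), " protein genes; possible",
      " synonymous = ", x$totals[["possible_synonymous"]],
      ", nonsynonymous = ", x$totals[["possible_nonsynonymous"]], "\n",
      sep = "")
  invisible(x)
}
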