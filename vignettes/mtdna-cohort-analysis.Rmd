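---
title: "Cohort-scale mitochondrial DNA characterization and association scanning with mitocohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-scale mitochondrial DNA characterization and association scanning with mitocohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocohort)
```

## The scientific setting

Human mitochondrial DNA (mtDNA) is a 16,569-bp circular genome carrying
37 genes — 13 protein-coding subunits of the oxidative-phosphorylation
complexes, 22 tRNAs and 2 rRNAs — plus the non-coding control region
(D-loop). In people living with HIV, mtDNA integrity interacts with
apoptosis signalling and hence with the pool of CD4+ T cells, the cell
population whose recovery under antiretroviral therapy (ART) defines
treatment success. `mitocohort` implements a complete cohort analysis
of whole-mtDNA sequences and CD4 outcomes:

1. **Variant calling** of each participant genome against the revised
   Cambridge Reference Sequence (rCRS) coordinate system by global
   pairwise alignment;
2. **Annotation** of every substitution with gene membership, synonymy
   under the vertebrate mitochondrial genetic code,
   transition/transversion status and definiteness;
3. **Characterization metrics** — mutational diversity, volume,
   densities, relative diversity against the enumerated space of all
   possible substitutions, momentum, amino-acid change bias, and
   physicochemical-change prevalences;
4. **Stratified trend analysis** across the 16 gender × age-group ×
   immune-level subpopulations;
5. A **genome-wide association scan** of carrier status against CD4
   outcomes using least-absolute-deviation (median) regression with
   case-resampling bootstrap inference and Bonferroni correction;
6. A **synthetic-cohort generator** so that the whole pipeline is
   testable without access to any participant data.

## The reference model

Coordinates are 1-based rCRS positions, the universal "m.POS REF>ALT"
nomenclature. The control region wraps the origin (16024–16569 joined
with 1–576) and is stored as two arcs under one name. Genes are grouped
into seven *macrodivisions*: D-loop, RNRs (the two rRNAs), tRNAs, NDs
(the seven complex-I genes), COs (the three cytochrome-oxidase genes),
ATPs (ATP6/ATP8) and CYB.

**The bundled sequence is a synthetic stand-in.** The canonical
NC_012920 gene annotation shipped in
`inst/extdata/rCRS_features.tsv` is real; the nucleotide sequence in
`inst/extdata/synthetic_rCRS.fasta` is generated by
`make_synthetic_reference()` (background bases drawn from the human
mtDNA base composition, valid start/stop codon structure imposed on
every CDS, the position-3107 placeholder set to N) because the real
sequence could not be obtained in the offline build environment.
Consequently every *coordinate-dependent* behaviour — gene and
macrodivision lookup, codon-position arithmetic, strand handling, the
total size of the substitution space — is exact, while
*sequence-content-dependent* numbers (the synonymous/nonsynonymous
composition of the space, specific codons) are realistic but not those
of the real rCRS. Substituting the real FASTA restores full fidelity
with no code change: `load_reference("rCRS.fasta", "rCRS_features.tsv")`.

## The possible-substitution space

`enumerate_substitution_space()` classifies, for every coding position
and each of its three alternative bases, whether the change is
synonymous or nonsynonymous by re-translating the codon (light-strand
genes, i.e. ND6, are complemented first). Conventions that required a
decision:

* **Incomplete stop codons.** Five genes end in a partial codon (T or
  TA) completed to TAA by polyadenylation. The default (`"polyA"`)
  completes the codon with A's and classifies its genomic bases like
  any other; changes there are almost always nonsynonymous because
  they destroy the stop. The alternative `"exclude"` drops them. The
  choice is forced by arithmetic: the 13 CDS lengths *including* the 7
  incomplete-stop bases sum to 11,395 positions, i.e. 3 × 11,395 =
  34,185 possible substitutions, which is exactly the published total
  for this space — the `"exclude"` convention would give 3 × 11,388.
* **Overlapping genes.** A position inside two genes (ATP8/ATP6,
  ATP6/CO3, ND4L/ND4) contributes independently to each gene, and
  genome-wide totals are per-gene sums. The same arithmetic above
  forces this convention for the possible-space totals. For *observed*
  diversity, by contrast, a type in two genes counts once per gene but
  only once in genome totals, because per-gene tables require per-gene
  attribution while a genome-wide census must not double-count.
* **Stops and initiators.** Changes creating or destroying a stop codon
  are nonsynonymous (standard dN/dS convention); stop→stop changes are
  synonymous. Initiator codons get no special treatment. The N
  placeholder at 3107 (an rRNA position) is untranslatable and excluded
  wherever it would matter.
* **Bias denominators.** For every target amino acid, the enumeration
  also counts the possible nonsynonymous changes *to* that amino acid
  (stop codons excluded on both sides); these are the denominators of
  the amino-acid-change bias metrics.

## Variant calling

`global_align()` reproduces the classical EMBOSS-Needle setting: global
alignment with match +5, mismatch −4, gap open 10, gap extension 0.5.
Two engines share that scoring:

* `"needle"` delegates to `Biostrings::pairwiseAlignment()` — the
  canonical full Needleman–Wunsch implementation (≈4 s per genome
  pair);
* `"banded"` (default) is a compiled affine-gap aligner restricted to a
  diagonal band (half-width `max(64, 2·Δlength + 32)`), exploiting that
  cohort mitochondrial genomes are near-identical to the reference
  (≈0.2 s per genome). Tie-breaks are fixed (diagonal > gap-in-query >
  gap-in-reference) so alignments are deterministic. The test suite
  cross-checks the two engines on planted-variant genomes.

`extract_variants()` reports substitutions per reference position;
runs of gaps collapse to single insertion/deletion events that are
**left-aligned** against the reference, so homopolymer indels always
get the lowest coordinate — the deterministic normalization that makes
apply-then-call round trips exact. IUPAC mixture codes in the query
(e.g. A>R) are preserved as *ambiguous* substitution types: they count
toward plain diversity and volume but are excluded wherever a metric is
defined over *definite* substitutions (relative diversity, momentum,
amino-acid changes) and from the association scan. Query N calls, and
any column over the reference N placeholder, are no-calls rather than
variants. Indels are kept in descriptive diversity/volume but excluded
from association analyses, matching a design in which one sequencing
platform could not call indels reliably.

## Characterization metrics

For a cohort registry of distinct variant types (keyed by position,
ref, alt, kind) with per-type carrier counts:

* **Diversity** = number of distinct types per unit (gene,
  macrodivision, genome); **volume** = carrier-weighted count. At the
  individual scale the two coincide.
* **Diversity density** = diversity / sample size / unit length in kb.
* **Relative diversity** = observed distinct *definite* substitutions
  over the possible count from the enumerated space, per class (all,
  synonymous, nonsynonymous, transition, transversion); its *density*
  variant divides the observed count by the sample size.
* **Momentum** = the OLS slope (intercept included) of per-gene
  observed-definite-types/sample-size against the per-gene maximum
  possible number of substitutions of that class, across the 13
  protein-coding genes. Because any affine recoding of the predictor
  rescales the slope, the raw β is reported and its directional
  interpretation is left to the caller.
* **Amino-acid change bias** = observed distinct changes *to* each
  amino acid over the maximum possible changes to it; the density
  variant divides the observed count by sample size. "Prevalence"
  counts distinct change types, not carriers (a carrier-weighted
  variant exists under `weighted = TRUE`).
* **Physicochemical changes** map the 20×20 change matrix onto class
  schemes — a four-way acidity/polarity partition plus the IMGT
  hydropathy, volume, chemical, charge, hydrogen-bond and polarity
  classes, shipped as an editable fixture
  (`inst/extdata/aa_classes.tsv`) since property partitions vary
  between sources — and report ordered class-pair prevalences that
  normalize to 100%.

## Stratified trends

`stratify()` builds the 2 × 4 × 2 = 16 subpopulations from gender, the
ordinal age groups 17–29 / 30–44 / 45–59 / ≥60 and the immune split at
the pre-treatment CD4 count of 200 cells/µl. The ethnicity filter
restricts to the majority ethnicity before stratification; strata below
five members are flagged, not dropped — the original design enforced
the minimum through cohort selection, not analysis-time exclusion.
`age_trend()` fits plain OLS of a stratum-level metric against the
ordinal codes 1–4 (one point per age group, since results are reported
as one slope per stratum family; participant-level weighting is a
documented alternative, not the default). Bias-density distributions
between immune strata are compared by the two-sided Wilcoxon rank-sum
test, and per-sample substitution loads between sequencing platforms by
the Welch unequal-variance t-test.

## The association scan

Indels and ambiguous calls are excluded; carrier status is coded 0/1
(mtDNA is effectively haploid at the major-allele level, and prevalence
counting in carrier units is what makes "1% = 8 of 724" arithmetic
work). `prevalence_filter()` keeps substitutions with carrier
proportion strictly between 1% and 99%; in a 724-participant follow-up
cohort that means carrier counts from 8 to 716. The filter is computed
on the follow-up complete-case set and the same substitution list is
used in both outcome models, so `k` kept columns yield `2k` tests and a
Bonferroni threshold of `0.05/(2k)` — 287 columns give 574 tests and
8.71 × 10⁻⁵.

**Model specification.** Pre-treatment model: CD4 at diagnosis on
carrier + gender, age, ethnicity (majority vs minority), transmission
route (heterosexual reference, homosexual, other). Post-treatment
model: follow-up CD4 on carrier + the same covariates + pre-treatment
CD4, regimen class (zidovudine-based reference, stavudine-based,
other) and treatment duration (< 3 vs ≥ 3 months). Participants without
a follow-up measurement are excluded from the post-treatment model
only. A covariate level absent from an analysis subset would produce an
all-zero dummy; such columns are dropped with a message instead of
failing every model.

**Median regression.** The fit minimizes Σ|yᵢ − xᵢᵀβ| (quantile
regression at τ = 0.5), which is robust to the heavy-tailed,
heteroscedastic CD4 residuals that violate OLS assumptions —
`residual_diagnostics()` reports a Breusch–Pagan (Koenker studentized)
homoscedasticity test and a Shapiro–Wilk normality test on the OLS
residuals as the documented model-family gate. The solver is an exact
basis-exchange (Barrodale–Roberts-type) descent written for this
package because no quantile-regression implementation is available in
the build environment: an L1 optimum interpolates p observations, the
solver walks edge directions of the current vertex to weighted-median
breakpoints, and terminates only when all p directions certify
non-descent, i.e. at the linear-programming optimum (verified against a
brute-force p-subset enumeration oracle to 10⁻⁸ in the tests). Ties in
the line search break deterministically by row index.

**Inference.** Case-resampling bootstrap with B = 1,000 replications by
default: SE = SD of replicate coefficients, CI = β ± 1.96·SE,
t = β/SE, p = 2(1 − Φ(|t|)). The normal-approximation rule is used
because published coefficient tables of this design are internally
consistent under exactly this rule; a percentile CI is also returned.
SE is always reported non-negative with t = β/SE, regardless of how a
source table may have arranged those columns. Replicates whose design
is singular (e.g. a resample losing every carrier) are dropped and
counted, with a warning above 10%. Each substitution × outcome gets its
own RNG stream seeded from the master seed and the column key, making
scan results invariant to column order; point estimates are also
invariant to participant order, while bootstrap SEs depend on row order
only through the documented resampling-index semantics.

**Reduced-B caveat.** With B replications the bootstrap t-statistic
behaves approximately like Student-t with B − 1 degrees of freedom
rather than normal, which inflates far-tail p-values when B is small:
at the 574-test Bonferroni threshold (|z| > 3.92) the per-test
exceedance is ≈ 9.3 × 10⁻⁵ at B = 1,000 but ≈ 1.2 × 10⁻⁴ at B = 200.
Because simulation cost scales as columns × (B + 1), the
family-wise-error study in the test suite trades columns for
replications (fewer null columns, B = 500) so that reduced-B inflation
does not masquerade as a pipeline defect, and allows two binomial
standard errors around the nominal 5%; production scans should keep
B = 1,000.

## The synthetic cohort generator

`simulate_cohort()` draws a *stated world* chosen once to mirror the
marginal composition of a large East-Asian ART-naïve cohort: 74.18%
male; age-group probabilities 30.14/40.54/18.81/10.51%; 94.51% majority
(Han) ethnicity; heterosexual/homosexual/other transmission at
69.04/28.62/2.34%; zidovudine-based/stavudine-based/other regimens at
77.07/16.30/6.63%; 40.33% treated under three months; 724/856 of
participants with a follow-up CD4. Pre-treatment CD4 is log-normal
with median 219 cells/µl and σ(log) = 0.506, reproducing the 149–295
interquartile range. The follow-up outcome is

> cd4_post = cd4_pre + 70 + Σ effectⱼ·carrierⱼ + covariate effects +
> Laplace(0, 94), truncated at 0,

so the median change is 70 cells/µl and the change IQR ≈ 2·94·ln 2 ≈
130 cells/µl, matching the reported 12–142 range. Laplace noise is the
default deliberately: it is the heavy-tailed world that motivates
abandoning OLS for median regression and it exercises the diagnostics
gate. Carriers are sampled independently per variant and participant
(no linkage or haplogroup structure — the analysis treats substitutions
marginally); 4% of substitution calls are emitted as IUPAC mixture
codes, matching the reported ~96% definite fraction. Planted indels are
stored in left-aligned canonical form and planted events are kept ≥8 bp
apart so the ground-truth ledger matches the caller's normalized
output exactly. Sequence realism beyond this — mutational spectra,
phylogeny, heteroplasmy — is explicitly out of scope, so a green
round-trip test establishes the calling/annotation machinery, not
biological realism of the genomes.

Uniform sampling over sense codons (with the human mtDNA base
composition for non-coding background) was chosen for the synthetic
reference; its synonymous share of the substitution space (8,050 of
34,185) is therefore close to, but not equal to, the real sequence's
published 8,291 — the structural total 34,185 is exact, the split is
not, and the acceptance suite documents that residual rather than
hiding it.

## Numerical choices and degenerate inputs

* LAD solver tolerances: directional-derivative threshold 10⁻¹¹,
  breakpoint cut-off 10⁻¹², Sherman–Morrison refactor every 50 pivots
  plus a canonical solve at the final vertex.
* Bootstrap SE of exactly zero (noiseless outcomes) yields a flagged
  degenerate result with `p = NA` instead of a spurious zero p-value.
* `prevalence_filter` uses strict inequalities on proportions, which is
  what makes the published count bounds exact.
* Wilcoxon p-values are exact for small tie-free samples and
  tie-corrected normal otherwise (the `stats::wilcox.test` rules);
  Shapiro–Wilk is subsampled above 5,000 observations.
* Constant-outcome diagnostics return an error-free degenerate report.

## Known limitations

* The bundled reference sequence is synthetic (see above); analyses of
  real cohorts must supply the real rCRS FASTA.
* No heteroplasmy fractions, quality scores, haplogroup calling or
  nuclear-mitochondrial pseudogene detection; a haplogroup label can be
  stored in metadata but is never computed.
* The scan models substitutions marginally with fixed covariates — no
  mixed models or population-structure correction beyond those
  covariates.
* The banded aligner assumes near-identity to the reference; highly
  divergent or rearranged genomes should use the `"needle"` engine.
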