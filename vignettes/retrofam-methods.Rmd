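---
title: "Methods and design of retrofam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of retrofam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrofam)
```

retrofam characterizes families of LTR retrotransposons (LTR-RTEs) in a
genome starting from curated reference elements. This vignette explains the
models the package implements, the assumptions behind them, the tunable
parameters, and the design decisions taken where the methodology was
genuinely open. It is the package's own account of its science, in the
spirit of the long-form vignettes of DESeq2 or vegan.

## 1. The biological models

### Copy mining and structural validation

A full-length LTR-RTE copy is defined operationally: a genomic locus that
aligns to a reference element over **at least 80 % of the reference length
with more than 80 % identity**, begins with the canonical `TG` dinucleotide
at the 5' LTR start and ends with `CA` at the 3' LTR end, and (for the
stricter "intact" criterion used in dating) is flanked by an exact target
site duplication (TSD) of 4--6 bp. `find_copies()` discovers loci by
seed-and-extend: exact 12-mer seeds on both strands are chained by their
implied locus start, and each chained candidate is aligned to the reference
by banded local alignment. Identity is matches / alignment columns
(internal gaps count, terminal gaps are excluded); coverage is the aligned
fraction of the reference. Copies failing a filter are retained with an
explicit rejection status (`rejected_identity`, `rejected_coverage`,
`rejected_termini`) so that filter effects are auditable.

LTR boundaries are not discovered de novo: the pipeline always has a
reference with annotated LTRs, so `delimit_ltrs()` projects the reference
LTR boundaries through the alignment onto the copy and refines the outer
boundaries within ±3 bp. Refinement scores each candidate shift by the
terminal motif (`TG`/`CA`) *plus* direct-repeat agreement -- an 8-mer
comparison against the projected partner-LTR boundary. The second term
matters: a TSD or flank can contain a chance `TG`, and motif-only
refinement would then snap to the wrong position; the true boundary also
matches the other LTR, a chance motif does not.

### Family classification and naming

Families follow the 80-80-80 convention: two LTRs belong to the same
family when a global alignment shows **at least 80 % identity over at
least 80 % of the shorter LTR**. `assign_families()` builds the graph of
qualifying pairs and takes its connected components (single linkage), so a
chain A--B--C is one family even when A and C fall below the threshold.
Families are numbered by descending member count. Names are assembled by
`name_family()` as superfamily prefix (`RLC` for *Copia*, `RLG` for
*Gypsy*), a host code such as `eg`, the lineage, and the family index,
e.g. `RLC_egAle_1`. Lineages are assigned by nearest K2P distance to a
labeled reference panel (`assign_lineage()`), a deliberate simplification
of maximum-likelihood phylogeny placement: distances beyond a ceiling
(default 0.6 substitutions/site) or saturated against the whole panel give
`"unclassified"`, and exact ties are reported as ambiguous rather than
silently broken.

### Insertion-time dating

The two LTRs of an element are identical at integration; afterwards each
accumulates substitutions independently at the neutral rate *r*. The
package aligns the 5' and 3' LTR globally, estimates their divergence
under the Kimura two-parameter model,

$$K = -\tfrac{1}{2}\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big],$$

with *P* and *Q* the transition and transversion proportions over gap-free
columns (pairwise deletion), and converts it to years as

$$T = \frac{K}{2r}, \qquad r = 1.5 \times 10^{-8}
\ \text{substitutions site}^{-1}\,\text{yr}^{-1}.$$

The factor 2 reflects that both LTRs evolve, so their mutual divergence
grows at $2r$ per year. Saturated estimates ($1-2P-Q \le 0$ or
$1-2Q \le 0$) are reported as missing, never clamped; downstream summaries
skip them. Per-family LTR diversity (`ltr_diversity()`) is the mean
pairwise per-site difference (an uncorrected p-distance, matching how
nucleotide diversity Pi is conventionally reported), with its standard
deviation across pairs.

### qPCR quantification

Efficiency comes from a dilution-series standard curve: ordinary least
squares of mean Ct on $\log_{10}$ concentration gives slope *y*, and

$$E = \big(10^{-1/y} - 1\big) \times 100\,\%,
\qquad \text{fold} = 1 + E/100 .$$

The anchor is built in: a slope of $-\log_2 10 \approx -3.3219$ cycles per
ten-fold dilution gives exactly $E = 100\,\%$ and a per-cycle fold of 2.
Relative copy number uses the comparative $2^{-\Delta\Delta C_t}$ method
against a single-copy reference gene; relative expression uses the
efficiency-corrected form $(1+E)^{-\Delta\Delta C_t}$ normalized to a
stable gene, with the calibrator defaulting to the sample with the highest
normalized Ct (the lowest-expression tissue), whose relative quantity is
exactly 1. The exponent sign is fixed so that lower Ct (more template)
always yields a higher quantity. Technical replicates are averaged at the
Ct level before any $\Delta$ computation; reactions with efficiency below
90 % are refused by default (`min_efficiency`). Normalizer stability is
the geNorm M statistic -- for gene *j*, the mean over other genes *k* of
the SD across samples of $\log_2(x_j/x_k)$ -- with the conventional
M < 0.15 single-gene sufficiency reading left to the user. Group
comparisons use one-way ANOVA followed, only when the omnibus test is
significant, by Fisher's LSD pairwise t tests on the pooled MSE with
compact letter groupings; no further multiplicity correction is applied,
matching standard practice for this design.

### Dominant-marker diversity

IRAP/REMAP bands are dominant binary markers. Similarity is the Jaccard
coefficient $GS_j = a/(a+b+c)$ (shared absences carry no information and
are excluded); clustering is textbook UPGMA with cluster-size-weighted
average linkage, each merge placed at half the cluster distance per side,
producing an ultrametric dendrogram exportable as Newick.
`polymorphism_stats()` reports scorable and polymorphic band counts per
species and primer. `read_band_calls()` turns per-lane fragment-size lists
into a locus matrix by chaining sizes that agree within ±2 %.

## 2. The synthetic-data generator

Every stage is testable without external data because the generator plants
known truth:

* **Genomes and insertions.** A background genome of i.i.d. bases at a
  configurable GC content receives element copies built from a reference
  with byte-identical `TG..CA` LTRs. Planting realizes the dating
  assumption exactly: each LTR is evolved *independently* with branch
  length $rT$ under the full K80 Markov process (back-mutations and
  multiple hits included, so the estimator's model is the simulator's
  model), the internal region evolves at the same rate, and the insertion
  is flanked by an exact duplication of the target site. The TSD length is
  4--6 bp (configurable), the canonical LTR-RTE range. The terminal two
  bases of each LTR are exempt from mutation by default
  (`mutate_termini = FALSE`) so termini checks can be tested independently
  of age.
* **Ct tables.** $C_t = \text{baseline} - \log(\text{quantity}) /
  \log(1+E)$ plus homoscedastic Gaussian noise, with a technical-replicate
  structure -- the simplest model consistent with triplicate wells.
* **Marker matrices.** Loci are fixed-within / variable-between species at
  configurable rates, so intra-species Jaccard similarity exceeds
  inter-species similarity by construction.

What the generator does **not** emulate: solo LTRs from unequal
recombination, nested insertions, indel evolution (substitutions only),
rate heterogeneity along the element, sequencing error, and gel-scoring
error in markers. Passing tests therefore demonstrate correctness of the
algorithms under the stated models, not robustness to every artifact of
real assemblies or real gels; in particular the mining
recall/precision results say nothing about diverged, truncated or nested
copies beyond the rejection statuses explicitly exercised.

## 3. Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere, in memory and on disk
  (the IRanges/GFF3 convention). A single convention across the whole
  stack was judged less error-prone in R than a 0-based internal
  representation, since every container the package touches (`substr`,
  IRanges, GRanges, GFF3) is 1-based.
* **Alignment scoring** is fixed package-wide: match +1, mismatch -1, gap
  open -3, gap extend -1, a gap of length L costing
  $-3 - (L-1)$. Traceback ties prefer diagonal, then gap in the first
  sequence, then gap in the second, so alignments are bit-reproducible.
  `N` never matches anything (it scores as a mismatch and fails
  termini/TSD comparisons).
* **Seed chaining** breaks candidate clusters when consecutive implied
  start positions differ by more than 200 bp. The threshold is deliberately
  tight: because reference LTRs are identical, every locus also produces
  two spurious LTR-sized diagonals offset by roughly the element length,
  and a loose threshold can fuse the true diagonal of one locus with the
  spurious diagonal of a close neighbor. Overlapping candidates are then
  resolved best-score-first within a reference (a sub-alignment can never
  displace the full locus) and best-identity-first across references (ties
  to the longer reference).
* **80-80 coverage denominator** for family classification is the shorter
  LTR's length -- the conservative choice where the convention is silent.
* **Saturation and degeneracy** are explicit: saturated K2P distances are
  `NA` with a flag; ANOVA on data with zero within-group variance is
  flagged degenerate and reported as an exact separation test (p of 0 or
  1) instead of dividing by a zero MSE; Jaccard pairs with no bands in
  either individual are `NA` with the pair list attached; zero-band
  individuals are dropped from similarity with a warning rather than
  imputed.
* **UPGMA determinism**: labels are processed in lexicographic order, so
  equal-distance ties resolve to the smallest labels; Newick children are
  ordered by smallest leaf label; branch lengths are written at full
  precision.
* **Simulation sizes in the test suite** (500 kb genome with 30 planted
  copies across 3 families; 100 dating replicates per age at 1 kb LTRs;
  1000 random points for closed-form checks) were chosen as the smallest
  designs at which the Monte-Carlo standard errors are tight enough for
  3-SE recovery checks to be meaningful.

## 4. Known limitations

* Mining is reference-guided; it cannot discover families absent from the
  reference panel, and de novo LTR detection is out of scope.
* Lineage assignment by nearest reference distance can differ from
  maximum-likelihood tree placement near the classification ceiling.
* The K2P clock converts divergence to years only as accurately as the
  assumed rate *r*; reported ages scale inversely with it.
* Dominant markers carry no heterozygosity information; Jaccard/UPGMA
  summaries describe band-sharing, not allele frequencies.

## 5. A worked micro-example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42, genome_length = 1e5)
refs <- list(
  simulate_reference_element("RLC_egA_1", "Copia", "A", 800, 2000, seed = 1),
  simulate_reference_element("RLG_egB_1", "Gypsy", "B", 600, 2500, seed = 2))
sim <- simulate_genome(cfg, refs, n_copies = c(4, 3),
                       ages = c(1e6, 2e6, 0.5e6))
copies <- mine_genome(sim$genome, refs, genome_id = "chr1")
ages <- lapply(seq_len(nrow(copies)), function(i)
  date_element(copies[i, ], sim$genome))
```

The same pattern at larger sizes underlies `scripts/acceptance.R`, which
recomputes every headline quantity of the pipeline from scratch.
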