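# retrofam

Characterization of LTR retrotransposon (LTR-RTE) families from reference
elements, for genome and molecular-marker studies of plant repeats — the
kind of analysis done when a handful of curated full-length *Copia* and
*Gypsy* elements must be turned into genome-wide copy catalogs, family
assignments, insertion-age distributions, copy-number and expression
estimates, and marker-based diversity summaries.

The package implements, as tested reusable functions:

* **Copy mining with structural validation** — seed-and-extend search for
  copies covering ≥ 80 % of the reference at > 80 % identity, with
  reference-guided LTR delimitation, the canonical `5'TG..CA3'` termini
  rule, and target-site-duplication (TSD) detection;
* **Family classification** — the 80-80-80 rule (≥ 80 % identity over
  ≥ 80 % of the shorter LTR, single linkage) with standardized names such
  as `RLC_egAle_1`, and nearest-reference lineage assignment;
* **Insertion-time dating** — inter-LTR divergence under the Kimura
  two-parameter model, `K = −½ ln[(1−2P−Q)√(1−2Q)]`, converted to years by
  `T = K/2r` with `r = 1.5 × 10⁻⁸` substitutions·site⁻¹·yr⁻¹, plus
  per-family LTR nucleotide diversity (Pi);
* **qPCR quantification** — standard-curve efficiency
  `E = (10^(−1/slope) − 1) × 100 %`, relative copy number by
  `2^(−ΔΔCt)`, efficiency-corrected expression `(1+E)^(−ΔΔCt)` with the
  lowest-expression calibrator, geNorm M normalizer stability, and one-way
  ANOVA with Fisher's LSD letters;
* **Dominant-marker diversity** — Jaccard similarity `GSj = a/(a+b+c)` on
  IRAP/REMAP band matrices, UPGMA dendrograms (Newick export), and
  polymorphism summaries;
* **A synthetic-data generator** — genomes with planted insertions of
  known family, age, termini and TSD; simulated dilution-series and sample
  Ct tables; species-structured marker matrices — so the whole pipeline is
  testable with known truth.

Sequence I/O uses Biostrings (FASTA) and rtracklayer (GFF3); pairwise
alignment is an exact Needleman–Wunsch/Gotoh implementation in C++ with a
fixed scoring scheme so identities are bit-reproducible.

## Worked example

Simulate a 100 kb genome with seven planted copies of two families, mine
it, and date every intact copy:

```r
library(retrofam)

cfg  <- sim_config(seed = 42, genome_length = 1e5)
refs <- list(
  simulate_reference_element("RLC_egA_1", "Copia", "A", 800, 2000, seed = 1),
  simulate_reference_element("RLG_egB_1", "Gypsy", "B", 600, 2500, seed = 2))
sim    <- simulate_genome(cfg, refs, n_copies = c(4, 3),
                          ages = c(1e6, 2e6, 0.5e6))
copies <- mine_genome(sim$genome, refs, genome_id = "chr1")
fl     <- copies[copies$status == "full_length", ]
ages   <- sapply(seq_len(nrow(fl)),
                 function(i) date_element(fl[i, ], sim$genome)$T)
```

which prints (alongside the simulator's truth):

```
          copy_id    family identity   tsd T_years true_age
 RLC_egA_1_hit001 RLC_egA_1    0.992 TATCA  336020    5e+05
 RLG_egB_1_hit001 RLG_egB_1    0.984 GCGAC 1021226    1e+06
 RLC_egA_1_hit002 RLC_egA_1    0.983 GAACG 1022068    1e+06
 RLC_egA_1_hit003 RLC_egA_1    0.972 CTCCG 2316994    2e+06
 RLC_egA_1_hit004 RLC_egA_1    0.982 AAGGG 1285083    1e+06
 RLG_egB_1_hit003 RLG_egB_1    0.971 ATACC 2160158    2e+06
 RLG_egB_1_hit004 RLG_egB_1    0.992 CCACC  735209    5e+05
```

Every planted copy is recovered full-length with its exact TSD; the
estimated ages scatter around the planted ages with the sampling noise
expected from ~800 bp LTRs (single-copy K2P estimates are noisy; means
across copies converge to truth). Per-family LTR diversity on the same
mined set:

```
LTR diversity RLC_egA_1: Pi = 0.0329 (sd 0.0114, 4 sequences)
```

A noiseless ten-fold dilution series recovers the canonical efficiency
anchor:

```r
fit_standard_curve(simulate_dilution_series(efficiency = 1, noise_sd = 0))
#> standard_curve: slope -3.3219, intercept 12.00, R^2 1.0000, E = 100.0%, fold 2.000
```

See `vignettes/retrofam-methods.Rmd` for the models, assumptions and
design decisions, and the help pages (`?find_copies`, `?date_element`,
`?assign_families`, `?expression_rq`, `?upgma`, ...) for the full
interfaces.

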