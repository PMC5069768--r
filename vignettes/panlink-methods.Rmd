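---
title: "Linking pan-genomes and pan-metabolomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking pan-genomes and pan-metabolomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panlink)
```

## The problem

Closely related bacterial strains — here modelled on a collection of
thirteen marine *Pseudoalteromonas*-like isolates falling into two clades —
can differ enormously in the secondary metabolites they produce even when
16S identity suggests a single species. `panlink` implements an integrated
mining workflow that treats the genomic and the chemical side of such a
collection with the same currency: a strains × entities presence/absence
matrix, where an entity is either a gene family or an aligned molecular
feature (neutral mass, retention time). Cross-examining the two matrices
proposes which biosynthetic gene cluster makes which metabolite family
before any compound is isolated.

The workflow stages are:

1. **Metabolome ingestion** (`subtract_blanks`, `align_features`,
   `merge_modes`, `top_n_by_intensity`): per-sample feature lists are
   cleaned of medium components, aligned across samples by mass/RT
   tolerance, merged across ESI⁺/ESI⁻, and reduced to a presence matrix.
2. **Pan/core analysis** (`pan_core`, `cluster_order`,
   `unique_and_shared_fractions`, `subset_coverage`): accumulation curves
   and diversity fractions for either matrix.
3. **Gene families and barcodes** (`pairwise_hits`, `build_families`,
   `bbh_orthologs`): the 50/50 family rule (identity > 50% over ≥ 50% of
   the longer gene, single linkage) and per-gene presence/absence barcodes
   from bidirectional best hits (BBH).
4. **OBU grouping** (`group_obus`, `merge_partials`): predicted pathways
   collapse into operational biosynthetic units when ≥ 80% of the genes of
   the smaller pathway have homologues at ≥ 60% identity; all-partial
   units with an identical conservation pattern are absorbed.
5. **Chemotype ↔ genotype linking** (`genes_matching_pattern`,
   `call_clusters`, `features_matching_pattern`, `match_significance`): a
   metabolite family's strain pattern probes the gene barcodes; matching
   genes that sit adjacent on one contig are candidate clusters.
6. **Halogen screen** (`defect_window_pass`, `isotope_pattern`): a linear
   mass-defect window (intercept 0.0937 Da, slope −0.02 Da per 100 Da,
   tolerance ± 0.0100 Da) flags polyhalogenated candidates; simulated
   isotope envelopes confirm them.
7. **Molecular networking** (`modified_cosine`, `build_network`): modified
   cosine > 0.7 links MS/MS spectra into molecular families.
8. **GA/SVM feature selection** (`ga_select`, `loo_fitness`): a genetic
   algorithm (population 25, 10 generations, mutation rate 1) wraps a
   linear SVM (cost 100, balanced class weights) scored by leave-one-out
   accuracy, reducing the 500 most intense features to 50 discriminators.

`run_all()` executes the stages in dependency order on a synthetic world
and `compare_to_ledger()` scores the outcome against planted truth.

## The synthetic planted world

Real inputs of this kind come from deposited draft assemblies and raw LC-MS
runs that are far beyond desk scale, so the package ships a seeded
generator (`generate_world`) whose defaults encode the emulated study
conditions at a reduced problem size:

* 13 strains in a 6 + 7 clade split with one near-clonal pair that shares
  almost all accessory families;
* a pan-genome of ~150 families chosen so the *composition* matches the
  emulated collection — about one third core families and one quarter
  singletons — rather than the absolute per-strain gene count (~5,100 in
  the real collection, ~80 here). Protein families descend from random
  ancestors (length 150–600 aa) with per-site substitution probability
  0.15 per branch, which keeps within-family pairwise identity near 70%
  (comfortably above the 50/50 rule) and cross-family identity at random
  (~5%, always failing it);
* ~300 consensus features per strain with 2% core and 30% unique features,
  drawn over 150–900 Da and 0.5–20 min with log-normal intensities;
  features are kept ≥ 0.05 Da or ≥ 0.5 min apart so tolerance-based
  alignment is well-posed;
* one 11-gene cluster planted contiguously in the 7-strain clade with a
  6-member linked molecular family and 40 halogen-defect features in
  total, plus one 13-gene cluster in three strains — mirroring the two
  discovery stories the workflow is built around. Cluster blocks are
  hosted on the largest available contig, as real clusters sit inside
  full-size contigs;
* blank (medium) features injected into every sample and into dedicated
  blank samples; two replicate extracts per strain with a 5% per-replicate
  dropout probability;
* fragment spectra per planted family member sharing a scaffold whose
  high-mass peaks shift with the analogue mass, so the modified cosine
  links the family.

Halogenated masses are generated *inside* the screening window and
ordinary metabolite masses follow a CH₂-like positive defect trend that
stays outside it; sensitivity and false-positive rate of the screen are
therefore measured against construction, not fitted.

What the generator deliberately does **not** emulate: chromatographic peak
shapes, adduct/dimer chemistry, intensity batch effects, nucleotide-level
genomes, and realistic enzyme sequences. Passing tests show the *logic* of
every stage recovers planted truth under controlled noise; they do not
show that tolerances or thresholds are optimal for any particular
instrument.

## Numerical and design choices

* **Alignment tolerances** default to 20 ppm mass and 0.2 min RT; the
  upstream commercial alignment tool's exact algorithm is unspecified, so
  grouping is single linkage over tolerance edges (robust to small RT
  drift chains) and consensus masses are intensity-weighted means.
* **Presence rule**: a strain is positive for a feature if any replicate
  contains it (`any_replicate`); the stricter `all_replicates` rule is
  available.
* **Builtin alignment engine**: candidate protein pairs must share at
  least two 5-mers before Smith–Waterman scoring (BLOSUM62, gap open 10,
  extend 0.5); alignments below 100 score units are discarded. The score
  floor matters: without it, proteins lacking a true ortholog in a strain
  acquire weak random best hits that occasionally reciprocate and
  contaminate barcodes. External 12-column tabular reports can be imported
  instead (`read_blast_table`).
* **BBH ties**: exact best-score ties yield no best hit at all — the
  conservative reading of a nongreedy pairing. 1:1 ortholog groups require
  a complete pairwise BBH clique across all strains, which is why the
  group count can fall below the core-family count.
* **OBU denominator**: the gene fraction is measured against the smaller
  pathway, which tolerates contig-split partial predictions; both OBU
  thresholds are inclusive.
* **Cluster calling**: matching genes joined across at most 2 intervening
  non-matching genes (real clusters carry non-diagnostic genes), minimum 3
  genes; candidates rank by size. An empirical permutation null
  (`match_significance`) shuffles gene positions within contigs to gauge
  how surprising an observed adjacent run is.
* **Mass defect convention**: the published window parameters are honoured
  verbatim, but they do not reproduce the nearest-integer defects of known
  polybrominated compounds (a Br₄ compound sits near −0.29 Da), so the
  defect convention (`nearest_integer` vs `fractional_part`) and all
  window parameters are exposed as configuration.
* **Modified cosine**: square-root intensity transform, 0.3 Da fragment
  tolerance, ≥ 6 matched peaks per edge; pairing is greedy by descending
  intensity product (classic networking behaviour), with an exhaustive
  optimal-assignment mode kept for oracle tests.
* **GA semantics**: "mutation rate 1" is read as one random gene
  replacement per offspring per generation; "ratio 1" as balanced class
  weights. Elitism keeps the better half each generation; parents are
  drawn rank-weighted from the elite, a choice made because uniform parent
  choice lost planted markers noticeably often on calibration data.
  Intensities are log-transformed and columns standardised per training
  fold (never on the held-out sample).

## Problem sizes used in tests

The shipped tests run the full pipeline on 5-strain miniature worlds and
the recovery suite on twenty 13-strain default worlds; the acceptance
script repeats recovery on ten worlds and one full default-world pipeline.
These sizes were chosen so the whole suite exercises every stage, including
the all-vs-all alignment path, at interactive turnaround.

## A short worked example

```{r example, eval = FALSE}
world <- generate_world(world_config(seed = 1))
report <- run_all(world, stages = c("features", "families", "obu",
                                    "halogen", "link", "network"))
report
compare_to_ledger(report, world$ledger)
```

## Known limitations

* The builtin aligner is meant for desk-scale worlds (thousands of
  proteins); genome-scale collections should import external hit tables.
* Adduct and dimer deconvolution is out of scope during alignment; adduct
  arithmetic is provided only as constants for dereplication.
* Binary presence patterns drive the linking logic; correlation of
  continuous intensities with gene content is deliberately not attempted.
* The pan/core machinery asserts nothing about open- vs closed-pan-genome
  models; curves are descriptive.
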