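# panlink

Integrated mining of comparative genomics and untargeted metabolomics for
collections of closely related bacterial strains.

## The problem

A group of near-identical isolates (by 16S) can hide enormous chemical
diversity: in the marine *Pseudoalteromonas*-like collection this package
models, only ~2% of molecular features are shared by all strains while
~30% are unique to single strains, and the gene side mirrors it (about a
third of gene families core, a quarter singletons). `panlink` puts both
sides into one currency — a strains × entities presence/absence matrix —
and cross-examines them to propose which biosynthetic gene cluster makes
which metabolite family, before any compound is isolated.

Core machinery, in the field's standard notation:

* **Pan/core curves** — for strains added in order `s1..sn`,
  `pan[i] = |∪ first i strains|`, `core[i] = |∩ first i strains|`; input
  order from hierarchical clustering of presence profiles (Jaccard,
  average linkage).
* **Gene families (50/50 rule)** — genes joined when pairwise identity
  > 50% over ≥ 50% of the longer gene; families are connected components.
* **BBH barcodes** — per-gene bit strings over all strains from
  reciprocal unique best hits (score ties → no hit); 1:1 ortholog groups
  are full BBH cliques.
* **OBUs** — predicted pathways grouped when ≥ 80% of the smaller
  pathway's genes have homologues at ≥ 60% identity; all-partial units
  with identical conservation patterns merged.
* **Chemotype → genotype linking** — features restricted to a strain set
  define a barcode pattern; genes matching the pattern that lie adjacent
  on one contig (≤ 2 intervening genes, ≥ 3 members) are candidate
  clusters, with an empirical permutation p-value.
* **Halogen screen** — a feature of mass *m* passes when its
  nearest-integer mass defect lies within ± 0.0100 Da of
  `0.0937 − 0.02·m/100`; simulated isotope envelopes (e.g. Br₂ gives
  M : M+2 : M+4 ≈ 1 : 1.95 : 0.95) confirm candidates.
* **Molecular networking** — modified cosine (fragments match directly or
  offset by the precursor-mass difference) with edges above 0.7;
  connected components are molecular families.
* **GA/SVM selection** — a genetic algorithm (population 25, 10
  generations, mutation rate 1) wraps a linear SVM (cost 100, balanced
  weights) under leave-one-out validation to cut the 500 most intense
  features to 50 discriminators.

A seeded synthetic-data generator plants all of this with known ground
truth (gene clusters, linked metabolite families, halogenated masses,
analogue spectra) so the whole workflow is testable end to end without
any downloads.

## Worked example

```r
library(panlink)

world  <- generate_world(world_config(seed = 42))
report <- run_all(world, stages = c("features", "families", "obu",
                                    "halogen", "link", "network"))
report
#> run_report
#>   features:
#>     raw_rows: 11057
#>     blank_rows_removed: 1274
#>     positive: 731
#>     negative: 247
#>     merged: 780
#>     cross_mode_matched: 198
#>     core_fraction: 0.01794872
#>     unique_fraction: 0.2910256
#>   gene_pan: 151
#>   gene_core: 50
#>   gene_singletons: 39
#>   ortholog_groups: 50
#>   obus: 2
#>   halogenated_flagged: 40
#>   candidate_clusters: 10
#>   network_families: 2
#>   network_singletons: 10

compare_to_ledger(report, world$ledger)
#> $cluster_recovered
#> CLUSTER_A CLUSTER_B
#>      TRUE      TRUE
#> $family_jaccard
#> [1] 1
#> $barcode_exactness
#> [1] 0.9820513
```

Reading the numbers: the simulated 13-strain collection yields 780 merged
molecular features of which 1.8% are core and 29% strain-unique; the gene
side recovers 151 families (50 core, 39 singletons) and 50 one-to-one
ortholog groups. The mass-defect screen flags exactly the 40 planted
halogen-defect features, the two planted pathway groups come back as two
OBUs, and for both planted clusters the top-ranked candidate from
barcode–pattern probing is exactly the planted gene block
(`cluster_recovered` all `TRUE`). `barcode_exactness` < 1 reflects the
generator's 5% replicate dropout, not an alignment error.

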