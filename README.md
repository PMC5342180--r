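# pugmark

Identify and sex pumas (*Puma concolor*) from left-hind footprints — a
footprint identification technique for non-invasive wildlife monitoring.

Footprints are the most ubiquitous sign a large carnivore leaves, and they
can be photographed cheaply by rangers, biologists and citizen scientists.
`pugmark` turns landmark coordinates placed on footprint photographs into a
morphometric fingerprint and answers the three questions a monitoring
program needs:

* **Are these two footprint trails from the same animal?**
* **How many individuals are in this set of trails?**
* **What sex made this footprint?**

## The method in brief

Each footprint is reduced to 25 landmark points plus 2 scale points; 15
more points are derived geometrically, and 128 variables are computed
(102 lengths in mm, 16 angles in degrees, 10 areas in mm²).

For a pair of trails $A$ and $B$, the classifier forms three groups —
$A$, $B$, and a **reference centroid group (RCV)** built from all the other
known individuals, which anchors the canonical space. Forward stepwise
selection by partial F-ratio picks the most discriminating variables
(default 15, selected on the reference individuals so the choice is blind
to the pair under test). Fisher canonical variates map every footprint to
the plane of the two leading eigenvectors of $W^{-1}B$; each trail centroid
receives a Hotelling-type confidence region with shape $S_t/n_t$ and scale
$c = \frac{2(n_t-1)}{n_t-2} F^{-1}_{2,n_t-2}(p)$ at contour probability
$p$ (default 0.95). **Verdict: same individual iff the two ellipses
overlap.**

Pairwise canonical centroid distances feed Ward clustering
(Lance–Williams); the dendrogram is cut at a threshold tuned to maximise
trail-placement accuracy on known animals, and the number of clusters is
the population estimate. Sex is classified by a stepwise linear
discriminant (default 20 variables, equal priors), validated by jackknife.

A hierarchical synthetic generator (`generate_population()`) emulates the
original captive study — 35 animals (19 F / 16 M), ~15 prints and ~2.3
trails per animal, individual landmark signatures (2 mm) well above
per-print noise (0.5 mm), 8% male size dimorphism — so the whole pipeline
is testable without the original data.

## A worked example

```r
library(pugmark)

pop <- generate_population(population_spec(n_individuals = 8, seed = 11))
cfg <- algorithm_config(seed = 1)
ingest_report(pop$table)
#> <ingest_report> 107 footprints, 8 animals, 19 trails (0 rejected)
#>   footprints/individual 13.38, trails/individual 2.375

compare_trails(pop$table, "A001_T1", "A001_T2", cfg)   # a true self pair
#> <pair_result> A001_T1 vs A001_T2: same
#>   centroid distance 1.654 | ellipses overlap (p = 0.95) | LOO self-assignment 87.5%
#>   variables: V119 V63 V87 V50 V47 V7 V93 V32 V55 V59 V60 V79 V19 V56 V99

pm <- pairwise_matrix(pop$table, cfg)
#> <pairwise_matrix> 19 trails, 171 pairs
#>   verdicts: 16 same, 155 different, 0 missing

hc <- ward_cluster(pm)
truth <- vapply(hc$labels, function(t)
  unique(pop$table$animal_id[pop$table$trail_id == t])[1], character(1))
th <- tune_threshold(hc, truth)
estimate_individuals(hc, as.numeric(th))
#> <census_result> 8 individuals at Ward threshold 9.586 (19 trails)

jackknife_accuracy(pop$table, n_vars = 20)   # sex classification
#> [1] 100
```

The 19 trails of 8 simulated animals produce 16 "same" verdicts (the true
self pairs, with a few borderline calls) and the tuned Ward cut recovers
exactly 8 individuals with 100% trail-placement accuracy; sex is fully
recoverable at the default dimorphism.

## Command line

An executable wrapper ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pugmark", package = "pugmark"))')
Rscript $CLI simulate --seed 17 --n-individuals 8 --out-table pop.csv
Rscript $CLI matrix   --table pop.csv --out-dist dist.csv --out-verdict v.csv
Rscript $CLI cluster  --matrix dist.csv --threshold auto --table pop.csv \
                      --out census.json --newick tree.nwk
Rscript $CLI sex train --table pop.csv --out model.json
Rscript $CLI holdback --table pop.csv --sizes 2,4 --seed 3 --out report.csv
```

Subcommands: `simulate`, `extract` (TPS/JSON landmarks → measurement CSV),
`compare`, `matrix`, `cluster`, `sex train|curve|predict`, `holdback`.
All stochastic commands take an explicit `--seed`, write it into a
provenance header, and are byte-reproducible.

## Data formats

* Measurement tables: CSV with `footprint_id, trail_id, animal_id, sex,
  age_years, side, V1..V128`; an XLSX dialect with a user-editable
  column-mapping file (`inst/extdata/s1_column_mapping.csv`).
* Landmarks: TPS (`LM=25`, coordinate rows, `SCALE=`) or an explicit JSON
  schema naming points `"01".."25"` plus scale points.
* Outputs: JSON (pair results, census, sex models), CSV (matrices,
  predictions, reports), Newick (dendrograms).
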