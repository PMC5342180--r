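---
title: "Identifying and sexing pumas from footprints: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and sexing pumas from footprints: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pugmark)
```

## The problem

Pumas (*Puma concolor*) are cryptic, wide-ranging, and expensive to monitor
invasively. Their footprints, however, are abundant, and footprint
morphometry carries enough signal to tell individuals — and sexes — apart.
`pugmark` implements a footprint identification technique built on three
statistical stages:

1. **Morphometry.** Each left-hind footprint photograph is reduced to 25
   landmark points plus two scale (ruler) points. Fifteen further points are
   derived geometrically, and 128 variables are computed: 102 inter-point
   lengths (mm), 8 angles at the intersection of two inter-point vectors,
   8 vertex angles (degrees), and 10 region areas (mm²).
2. **Pairwise trail classification.** A *trail* is an unbroken series of
   footprints from one animal. For any two trails the package decides "same
   individual" or "different individuals" with a canonical discriminant
   analysis of three groups — trail A, trail B, and a *reference centroid
   group* (RCV) assembled from the other known individuals — followed by a
   confidence-ellipse overlap rule in the first two canonical variates.
3. **Census and sex.** The matrix of pairwise canonical centroid distances
   feeds Ward agglomerative clustering; cutting the dendrogram at a tuned
   threshold counts individuals. A separate stepwise linear discriminant
   classifies footprints by sex.

A hierarchical synthetic-footprint generator makes every stage testable
without access to the original captive-animal dataset.

## The pairwise model

Write $x_{tf} \in \mathbb{R}^{128}$ for the measurement vector of footprint
$f$ in trail $t$. For a comparison of trails $A$ and $B$ against a library:

* **Reference group.** The RCV holds every library footprint of every animal
  *except* the owners of $A$ and $B$ (mode `all-other-animals`), or a copy
  of the whole table (mode `whole-table-duplicate`). Its role is to anchor
  the canonical space so that the $A$–$B$ geometry does not drift as other
  animals enter or leave the library.
* **Variable selection.** Forward stepwise selection by partial F-ratio
  picks `n_variables` (default 15; the technique is typically tuned in the
  14–20 band). At each step every remaining candidate is residualised on
  the already-selected variables and the one-way ANOVA F of the grouping is
  computed on the residuals with denominator df $n - g - q$.
* **Canonical variates.** With pooled within-group covariance $W$ and
  between-group scatter $B$ (over the three groups), solve
  $B a = \lambda W a$; the two leading eigenvectors, scaled so
  $a^\top W a = 1$, map all footprints to the plane.
* **Ellipses and verdict.** Each trail's centroid gets a confidence region
  with shape $S_t / n_t$ ($S_t$ the trail's score covariance) and scale
  $c = \frac{2(n_t - 1)}{n_t - 2} F^{-1}_{2, n_t - 2}(p)$, a small-sample
  Hotelling-type region at *contour probability* $p$ (default 0.95). The
  verdict is **same** exactly when the two regions intersect (containment
  counts); the ellipse-overlap test is exact, via the point-to-ellipse
  secular equation after mapping one ellipse to the unit disk.

The three tuning elements of the technique — number of variables, contour
probability, Ward threshold — live in `algorithm_config()`.

### Where the selection looks: a deliberate design choice

The natural reading "re-run stepwise selection on the three groups of every
pair" turns out to be statistically unsound: with ~6 footprints per trail
and 128 candidate variables, selection maximises the *apparent* separation
of trail A from trail B, so even two halves of the same trail are driven
apart. On synthetic populations at default settings this costs roughly half
of all self-pairs (same-animal pairs misclassified as "different") and
produces a null false-"different" rate near 45%.

`pugmark` therefore defaults to `selection_scope = "reference"`: the
stepwise selection runs on the reference rows only, grouped by individual.
The selected set is then a property of the library of known individuals —
a *species algorithm* — and is blind to the pair under comparison. The
trails to be compared influence only the canonical rotation and the
ellipses, not which measurements are used. `selection_scope = "pair"`
retains the literal per-pair behaviour for comparison.

### What the ellipse test does and does not control

Even with reference-scoped selection, the two canonical axes are re-fitted
per pair *with the two trails as groups*. Under exchangeability (no true
individual differences) the fitted axes chase whichever directions happen
to separate the two trails in the 15-variable space, so the null
probability that two level-$p$ centroid regions are disjoint is inflated
above the $2(1-p)$ Bonferroni bound that would hold for a fixed projection
— we measure roughly 15–25% at $p = 0.95$ instead of $\le 10\%$. A dim-2
F quantile cannot absorb a selection made in 15 dimensions, and the honest
simultaneous (Hotelling, dimension-15) constant is undefined at trail sizes
of 4–8. This residual anti-conservatism is a property of the centroid-plot
design itself; it is documented here, asserted honestly in the acceptance
suite (where the corresponding check is expected to fail), and it matters
little in the operating regime, where individual signatures dwarf noise and
both self- and non-self accuracy exceed 90%.

## Census by Ward clustering

`pairwise_matrix()` fills the symmetric matrix of canonical centroid
distances; `ward_cluster()` applies Ward's minimum-variance agglomeration
(Lance–Williams update on the distances as given). `tune_threshold()`
grid-searches the dendrogram cut that maximises trail-placement accuracy on
animals of known identity — clusters are matched one-to-one to animals by
maximum-weight bipartite assignment, so the metric is label-invariant and
does not reward splitting; ties resolve to the smallest threshold.
`estimate_individuals()` cuts at the threshold and counts clusters.
`likelihood_profile()` is a bootstrap rendering of the interactive
"relative likelihood" display: footprints are resampled within trails, the
census is recomputed, and each candidate count is scored by its bootstrap
frequency relative to the modal count. The resampling construction is this
package's convention; the original software does not document its test.

## Sex classification

`fit_sex_model()` runs the same stepwise engine with the two sexes as
groups, then a two-class linear discriminant with pooled covariance and
*equal priors* regardless of the training imbalance (19 females vs 16
males in the study structure). The default of 20 variables matches the
plateau of the accuracy-versus-variable-count curve (`accuracy_curve()`);
a fixed 20-variable preset from the published variable table
(`preset = "table1-sex"`) and a 10-variable option are provided because
the source is ambiguous between 10 and 20.

Validation is leave-one-footprint-out (`jackknife_accuracy()`). By default
the variable selection is held fixed from the full data and only the
discriminant is refitted per fold; `strict = TRUE` re-selects inside every
fold. The fixed-selection mode is anti-conservative under the null — the
held-out footprint helped choose the variables, which is worth ~5
percentage points of spurious accuracy on exchangeable data — so the
null-calibration acceptance check uses the strict mode. On dimorphic data
both modes agree to within a point.

Two further caveats the synthetic experiments make visible:

* **Individual leakage.** With strong individual signatures, other prints
  of the held-out animal remain in the training fold, and a rich
  discriminant can classify "which animals are male" rather than "what
  makes a print male". Jackknife accuracy on print level is therefore an
  optimistic estimate of performance on unseen animals.
* **Age.** The generator draws age independently of sex; permuting the age
  column never changes predictions (asserted in the tests), mirroring the
  original study's check that sex determination is not an age effect.

## The synthetic world

`generate_population()` simulates landmark configurations as
$P = s_{\text{sex}} (T + D_i) + \delta \cdot U \cdot [\text{male}] + E_f$:

| Parameter | Default | Meaning |
|---|---|---|
| `T` | `puma_template()` | fixed 25-point left-hind template (~90 mm print; toe 3 longest, toes skewed inward, trapezoidal pad) |
| `sigma_individual` | 2 mm | s.d. of the per-animal landmark offset $D_i$, drawn once per animal |
| `sigma_noise` | 0.5 mm | s.d. of per-footprint noise $E_f$ (substrate, placement) |
| `male_scale` | 1.08 | male size factor $s_{\text{sex}}$ |
| `shape_shift` | 0.5 mm | magnitude $\delta$ of a fixed male shape field $U$ (broader pad, splayed outer toes) |
| `n_individuals`, ranges | 35; 1–4 trails, 4–8 prints/trail | emulates the study: 35 animals, ~15 prints and ~2.3 trails per animal |

`table2_layout()` reproduces the published collection exactly (19 F / 300
prints / 45 trails; 16 M / 235 prints / 34 trails). The 2 mm vs 0.5 mm
ratio encodes the technique's working assumption — individual signature
well above within-individual noise; the dimorphism defaults were chosen
once so that default sex classification lands in the study's ~99% regime,
and are documented as tunable conventions, not biological estimates.

The generator deliberately omits: substrate autocorrelation (noise is
isotropic Gaussian per landmark), gait/speed effects, perspective
distortion, and landmark placement error by the human operator. A green
synthetic test therefore establishes internal statistical correctness of
the pipeline under its stated assumptions, not field performance.

## Numerical choices and degenerate inputs

* Stepwise ties (including exact ties from collinear variables) break to
  the lowest variable index, with a relative tolerance of 1e-9 so that
  floating-point noise cannot flip an ordering; constant or collinear
  candidates are skipped with one warning.
* A singular pooled within-group scatter is ridge-regularised with
  $\varepsilon = 10^{-8}\,\mathrm{tr}(W)/p$ (absolute floor $10^{-12}$,
  escalating if needed), with a warning.
* A trail whose canonical scores have (near-)zero scatter — noise-free
  simulations, duplicated bootstrap rows — receives a tiny SPD floor on
  its ellipse shape instead of an error.
* Trails with fewer than 3 footprints cannot carry an ellipse and are
  excluded from pairwise analysis with a warning; trails of 3 or more are
  compared as-is (the F-based scale constant is small-sample correct).
* Selected-variable count is additionally capped at (rows − groups − 1).
* Calibration uses one scale distance; when a second ruler distance is
  supplied, factors disagreeing by more than 2% trigger an anisotropy
  warning (perspective distortion).
* Right-hind prints are mirrored on input and flagged; all geometry
  assumes the left-hind frame (+y toward the toes).

## Derived points: a versioned convention

The original software displays 15 derived points but does not publish
their constructions. The package fixes a documented table (see
`R/catalog.R`): midpoints of the four toe-base pairs and of opposing pad
boundary points, the toe-base centroid, the intersection of the pad axis
(point 22 to the anterior pad midpoint) with the outer distal toe line,
and projections of the toe flanks onto the pad axis. Constructions are
rotation/translation equivariant, deterministic, and error out by name
when a line intersection degenerates. No fidelity to the original tool's
exact constructions is claimed: the deposited measurement table already
contains computed variables, so reproducing the classification never
requires re-deriving them — only new-data use does, and that requires only
internal consistency.

One construction was revised during development: derived point 40 was
initially the midpoint of points 18 and 25, making one length variable an
exact half of another; it is now the midpoint of points 18 and 24 so that
all 128 variables are non-redundant.

## Validation design

`holdback_trial()` apportions *animals* (never trails) at random into
training and test sets over a range of test sizes, ten iterations each.
The Ward threshold is tuned on the training animals only, and the
reference group for test-trail comparisons is drawn from training rows, so
test animals never influence selection, anchoring, or tuning (asserted in
the tests by perturbing a test animal and checking the tuned threshold is
bit-identical). Per-iteration accuracy is
$100 - 100\,|\hat{k} - k|/k$ — the package's documented metric, since the
source reports headline percentages without a formula. The alternative
reading (reference from test rows) is available as `rcv_from_test`.

## Known limitations

* No image processing or landmark placement: the package consumes
  TPS/JSON landmark coordinates or ready measurement tables.
* The null behaviour of the ellipse-overlap verdict is anti-conservative
  (see above); population estimates from *sparse* libraries of short
  trails should be read as upper bounds on individual counts.
* The bootstrap likelihood profile resamples within trails only; it does
  not propagate uncertainty in the tuned threshold.
* The reader for the deposited spreadsheet dialect (`s1-xlsx`) ships with
  an editable column-mapping file because the deposited file's exact
  headers are not published; it requires `readxl` at run time.

## A worked example

```{r example, eval = FALSE}
library(pugmark)

pop <- generate_population(population_spec(n_individuals = 8, seed = 11))
cfg <- algorithm_config(seed = 1)

# one pairwise comparison
trails <- unique(pop$table$trail_id)
compare_trails(pop$table, trails[1], trails[2], cfg)

# full census
pm <- pairwise_matrix(pop$table, cfg)
hc <- ward_cluster(pm)
truth <- vapply(hc$labels, function(t)
  unique(pop$table$animal_id[pop$table$trail_id == t])[1], character(1))
th <- tune_threshold(hc, truth)
estimate_individuals(hc, as.numeric(th))

# sex
jackknife_accuracy(pop$table, n_vars = 20)
```

All numerical claims in this vignette (accuracies, null rates, recovery of
the true number of individuals) are computed by the test suite
(`tests/testthat/`, in particular `test-acceptance.R`) and by
`scripts/acceptance.R`; none are asserted from memory.
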