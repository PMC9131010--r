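---
title: "Measuring perceived psychological stress from streetscape composition: models and methods"
author: "urbanstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring perceived psychological stress from streetscape composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanstress)
```

## The measurement problem

Street-view imagery segmented into visual-element classes gives, for every
sample point of a road network, a 19-dimensional vector of coverage
fractions (road, sidewalk, building, wall, ..., sky, vegetation, car).
Perceived psychological stress is elicited from human raters on a bounded
0--100 instrument, extended to the full image set by a machine-learning
model, and then analysed as a spatial field: global and local Moran
statistics for clustering, natural-breaks levels for mapping, and a linear
regression linking stress back to the element coverages. This package
implements that whole chain, together with a synthetic-scene generator
rich enough to exercise every stage without imagery.

## The synthetic study

Because no rater scores or imagery ship with the package, all end-to-end
computations run on a generated study whose structure mirrors the target
analysis:

* **Road network and sampling.** `generateRoadNetwork()` draws random-walk
  polylines in a planar extent (meters); `pointsAlongNetwork()` places
  sample points every 50 m (default) at arc lengths $0, h, 2h, \dots$
  strictly below each segment's length. The half-open rule is a design
  choice: segment endpoints shared by junctions would otherwise be emitted
  twice. `enumerateViewRequests()` reproduces the collection protocol
  exactly (4 headings $\times$ fov 90° $\times$ pitch 6° $\times$ 640 px),
  so the request table for $n$ points always has $4n$ rows.
* **Scene composition.** Each point belongs to a scene archetype
  (residential, commercial, park, arterial). An archetype is a Dirichlet
  concentration over the 19 element classes plus a void pseudo-class;
  draws therefore satisfy the compositional constraint
  $\sum_k f_k \le 1$ by construction. The default archetype means echo
  the magnitudes seen in segmented street imagery (road $\approx 0.2$--$0.4$
  and sky $\approx 0.2$--$0.3$ dominant, building next, the remaining
  elements small). In the pipeline, archetypes are assigned by nearest
  seeded patch center, giving the block-by-block spatial coherence of a
  real district.
* **Latent stress field.** Scores are
  $y_i = \mathrm{clip}(\beta_0 + \beta^\top f_i + u_i,\ 0,\ 100)$ with
  $u = (I - \rho W)^{-1} \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$ —
  the standard simultaneous-autoregressive construction on the
  row-standardized weights, which makes spatial autocorrelation tunable
  through $\rho$. Defaults: $\beta_0 = 55$, $\rho = 0.7$, $\sigma = 5$
  score units. The ground-truth signs put walls (+80) and buildings (+60)
  stress-raising and sky (−40), vegetation (−35), grass/terrain (−30),
  road (−25), sidewalk (−15) and auto/car (−10) stress-lowering; the
  magnitudes were fixed once so that typical scenes land mid-scale, and
  they make the sign-recovery checks meaningful. Clipping is applied after
  noise, matching the bounded instrument.
* **Raters.** A `raterProfile()` scores a scene as a clipped noisy linear
  functional of its composition, drawing from a private seeded noise
  stream so whole sessions replay exactly. The pipeline instead uses
  `makeFieldRater()`, whose subjective score is a noisy reading of the
  latent field itself — raters respond to the environment, of which the
  composition is the observable part. Rater noise is a free parameter
  (default SD 3 in the pipeline): no published inter-rater variance exists
  for this instrument, so it is deliberately a knob, not a calibrated
  value.

What the generator does *not* emulate: perspective rendering, stitching
overlap between the four views, rater fatigue or timing, and
availability gaps in imagery. Passing tests therefore demonstrate the
statistical machinery, not the perceptual validity of any real-world
deployment.

## The adversarial scoring loop

`runScoringSession()` implements the human--machine protocol: the rater
scores 50 warm-up images presented in a seeded shuffled order; a random
forest (500 trees by default, `mtry` 6 $\approx p/3$, minimum node size 2)
is trained on them; from image 51 on, the model predicts and the rater
keeps scoring. When the absolute error exceeds 10 score units for 6
images *in a row* — the counter resets on any smaller error — the model
retrains on **all** subjective scores accumulated so far, and keeps
retraining image by image until an error below the threshold appears.
Final scores for every image come from the last model;
`consensusScores()` averages raters (uniform weights by default — no
published weighting exists, so uniformity is the neutral choice).

Two design points deserve note:

* **Bootstrap vs "two-thirds".** The forest uses the standard
  $n$-draws-with-replacement bootstrap, which leaves $\approx 36.8\%$ of
  samples out of bag — the familiar folklore reading of a
  "two-thirds in, one-third out" split. An exact without-replacement
  subsample (`sampleFrac = 2/3`) is available for users who want the
  literal split.
* **The importance indicator.** Permutation importance is defined here in
  indicator form: for tree $n$ and feature $j$,
  $VI_n(X_j) = \bigl[\sum_i I(f(X_i) \approx f_n(X_i)) -
  \sum_i I(f(X_i) \approx f_n(X_i'))\bigr] / N_{OOB}$,
  where $X'$ permutes feature $j$ within the tree's out-of-bag set and
  the agreement indicator is $|a - b| \le$ `agreementTol` (default 5
  score units) — the minimal adaptation of an exact-equality indicator to
  a continuous response. With tolerance $\infty$ every indicator is 1 and
  all importances vanish; with tolerance 0 they vanish almost surely.
  `mseImportance()` provides the standard mean-increase-in-MSE importance
  as an independent cross-check; the two agree on rankings in the tested
  scenarios.

## Spatial statistics

`buildWeights()` constructs fixed-distance-band weights: $w_{ij} = 1$ if
the Manhattan distance is at most the threshold (inclusive — so the
automatic threshold, the largest nearest-neighbor distance, guarantees
every point at least one neighbor *exactly*), 0 otherwise, then
row-standardizes. Row standardization breaks symmetry; every downstream
formula uses the asymmetric standardized weights, and $S_0$ is recorded
after standardization (equal to $n$ when no point is isolated).

Global Moran's I is
$$I = \frac{n}{S_0}\,
\frac{\sum_i \sum_j w_{ij} (x_i - \bar x)(x_j - \bar x)}
     {\sum_i (x_i - \bar x)^2},$$
with $E(I) = -1/(n-1)$ and a Z test. The variance defaults to the
closed-form **randomization** (permutation-moment) assumption, with the
normality closed form and a full permutation mode selectable: the
published analyses this package follows were produced with GIS tooling
whose default is randomization, and the suite's empirical size check
(type-I error within $[0.02, 0.10]$ at $\alpha = 0.05$ over 200 null
replicates) validates that choice directly.

Local statistics are $I_i = (x_i - \bar x)\, \sum_j w_{ij}(x_j - \bar x)
/ S^2$ with $S^2 = \sum_i (x_i-\bar x)^2 / n$, which makes
$\sum_i I_i = S_0 \cdot I$ an exact algebraic identity (tested to
$10^{-9}$). Significance uses conditional permutation (value at $i$ held
fixed, neighbors refilled without replacement from the remaining $n-1$
values; 999 draws; two-sided pseudo-p $(\#\{|I_i^*| \ge |I_i|\}+1)/(999+1)$),
and significant points are labeled HH/LL/HL/LH from the signs of the
centered value and its spatial lag. The Moran scatter slope equals $I$
when the weights are row-standardized with no isolates — also tested as
an identity.

## Classification and mapping

`jenksBreaks()` is an exact Fisher--Jenks dynamic program on distinct
values with multiplicities ($O(kn^2)$), chosen over the heuristic
reallocation variant for determinism and oracle-checkability (the suite
compares it against exhaustive enumeration for $n \le 12$). Boundaries
are class maxima; classification assigns the first class whose upper
bound covers the value, clamping out-of-envelope scores with a warning.
The six levels map onto tiers as 1--2 Low, 3--4 Medium, 5--6 High — the
grouping used in six-interval stress summaries. District means for
three-band coloring reuse Jenks with $k = 3$.

Hexagonal aggregation uses pointy-top axial coordinates anchored at the
bounding-box minimum, nearest-center assignment, and lexicographic
$(q, r)$ tie-breaks on boundaries — the orientation and tie rule are
arbitrary in the literature, so they are fixed here for determinism.

## Regression diagnostics

`olsFit()` regresses consensus stress on the eight most influential
elements (wall, building, sky, vegetation, road, grass, sidewalk, auto;
"grass" and "auto" are the terrain and car classes — the vocabulary is
reconciled once, in `elementAlias()`). It reports standardized betas
$b_j \, s_{x_j} / s_y$, per-coefficient t tests (no multiplicity
correction, mirroring how such tables are reported), VIFs from auxiliary
regressions, and the Durbin--Watson statistic. DW needs a case ordering
that analysis reports never state; the default is ascending point id
(acquisition order), configurable via the `order` argument of
`durbinWatson()`.

Because coverages are compositional, predictors are strongly collinear
(large buildings crowd out sky and road), so at small sample sizes the
weak coefficients (auto, sidewalk, grass) are unstable even when the
strong ones (building, sky, vegetation) are sharply estimated. The
sign-recovery property is therefore stated — and tested — at the
generator's study conditions: $n = 2000$ scenes, innovation SD 5, all
eight signs recovered in at least 18 of 20 seeded replicates.

## Numerical choices and degenerate inputs

* Constant score fields make Moran statistics undefined: explicit error.
* An explicit band threshold that isolates points warns and flags the
  isolates; a threshold isolating *all* points errors.
* Raster rendering apportions pixels by largest remainder (ties to the
  lower class id), bounding the per-class error by one pixel; the
  render/extract round trip is exact to $1/(wh)$ per class.
* Perfect regression fits have undefined DW (zero residuals): reported as
  `NA` inside `olsFit()`, an error when `durbinWatson()` is called
  directly.
* All generators take explicit integer seeds and restore the caller's RNG
  state; the pipeline derives per-stage seeds from one master seed by a
  stable name hash, so stages are independently reproducible.

## Problem sizes

The test suite and the acceptance script run the study at deliberately
modest sizes chosen for fast, deterministic verification: pipeline runs
of roughly 100--500 sample points, forests of 25--150 trees, 200
replicates for the size check, and 20 seeded replicates at $n = 2000$
for sign recovery. These sizes are the package's own verification
choices; the statistics themselves scale to district-sized studies
(tens of thousands of points) limited only by the dense distance matrix
in `buildWeights()`, which is quadratic in $n$.

## Known limitations

* The weights builder materializes a dense distance matrix; beyond
  $n \approx 2 \times 10^4$ points a tiled or tree-based neighbor search
  would be needed.
* The adversarial loop assumes the rater scores every presented image;
  protocols where raters only spot-check after warm-up would need a
  sampling rule the literature does not specify.
* GeoJSON support covers LineString/MultiLineString networks and
  Polygon/MultiPolygon outer rings with planar coordinates; holes and
  geographic (lon/lat) coordinates are out of scope — inputs must be
  pre-projected, since Manhattan-distance bands presume planar axes.
* Geary's C and Getis--Ord G are not implemented; kernel and k-nearest
  weights are not offered.
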