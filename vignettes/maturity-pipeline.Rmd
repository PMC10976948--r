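---
title: "Methods: the hyperspectral seed-maturity pipeline"
author: "hyperseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hyperspectral seed-maturity pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`hyperseed`, the assumptions behind them, the tunable parameters, and the
design choices made where the underlying methods leave room. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The problem

Seed maturity at harvest is heterogeneous — on oilseed rape, pods set and
ripen asynchronously, so a harvested lot mixes green, yellow and fully
mature seeds. Visible/near-infrared hyperspectral imaging separates these
stages non-destructively: pigment and moisture differences shift
reflectance, mostly in the 700–1,000 nm region. The pipeline turns raw
hypercubes (or already-extracted spectra) into a maturity classifier and a
systematic comparison of pretreatments, wavelength selectors and
classification models.

## Calibration and region-of-interest extraction

Raw counts are calibrated to percent reflectance against dark-current and
white-reference cubes, `(raw − dark)/(white − dark) × 100`. Pixels where
`white ≤ dark` have no usable dynamic range; they are set to `NA` and
counted in a warning rather than clipped, and per-seed means simply skip
them band-wise. Segmentation happens on the plane nearest 440 nm (band
lookup is by nearest wavelength, never by index, because header wavelength
lists are non-integer). Otsu's threshold is computed on a 256-bin histogram
of the plane; when a plateau of thresholds is equally good — the usual case
for well-separated seed/plate modes, where the histogram has an empty gap —
the plateau midpoint is returned, keeping the cut centred between modes.
Which side of the threshold is "seed" is not knowable a priori (seeds may
be darker or brighter than the plate), so the default polarity heuristic
picks the side with more, smaller connected regions; a flag overrides it.
Components are 8-connected, labelled in raster order of their first pixel,
and regions under `min_area` (default 20 px) are dropped as specks.
Extracted spectra are trimmed to the closed interval 420–982 nm, where
sensor noise is acceptable; "between 420 and 982 nm" is read as inclusive
endpoints.

## Pretreatments

Five row-wise operators and their stated combinations: Savitzky–Golay
smoothing, first and second derivatives, SNV, and polynomial detrend. The
chain grammar (`"sg+d1st"` etc.) accepts exactly the nine study variants
unless explicitly overridden.

* **SG** defaults to window 11, polynomial order 3 — a common chemometrics
  default rather than a dictated value, so both are exposed as parameters
  and recorded in the table's provenance.
* **Derivatives** are finite differences on the *wavelength grid* (central
  differences, one-sided/copied at the ends), so non-uniform grids do not
  distort results and units become %/nm and %/nm². The bare derivative is
  deliberately not an SG derivative: the derivative-alone and
  SG-plus-derivative chains are distinct treatments, which forces this
  reading.
* **SNV** standardizes each spectrum to mean 0, sd 1; a constant spectrum
  is an error naming the offending sample.
* **Detrend** subtracts the least-squares polynomial of degree 2 by default
  (the standard companion of SNV); being an orthogonal projection it is
  idempotent, which the tests assert.

## Splitting

Kennard–Stone selection is run independently inside each class at a 3:1
ratio: the first two picks are the maximally distant pair, every later pick
maximizes the minimum Euclidean distance to the chosen set, and all ties
break to the lowest sample index so the split is a pure function of the
data. Per-class training counts use round-half-up on `0.75·n`, which gives
300/300/525 (1,125 train / 375 test) for classes of 400/400/700. Distances
are computed on the table as given. The comparison grid computes **one**
split per master seed, on the trimmed untransformed table, and shares it
across all cells — per-chain splits would make cell accuracies
incomparable, and recomputing the split in a derivative feature space would
silently change the partition between cells.

## Wavelength selection

All selectors regress the numerically coded class labels (1/2/3) — their
internal criteria (RMSE, RMSECV) are regression criteria. CARS and IVISSA
use a SIMPLS partial-least-squares core (compiled, coefficients for all
component counts in one pass; component count picked by the same
cross-validation that scores the subset, capped at 10).

**SPA** builds, from *every* candidate start band, a chain that repeatedly
adds the band with the largest residual norm after projecting out the
already-chosen columns (columns are mean-centred first). Chains are
computed from the Gram matrix; subsets of size 10–100 are then scored by
validation RMSE of an ordinary least-squares fit on the selected bands,
evaluated incrementally via Gram–Schmidt so the whole (start × size) search
stays cheap. OLS here *is* the classical SPA phase-2 evaluator and equals
PLS at full rank; a per-subset PLS would add nothing but cost. Ties go to
the smaller subset, then the lower start band. The validation portion is a
seeded stratified 25% of the training rows.

**CARS** runs `n_mc = 1000` Monte-Carlo iterations per run and 5 runs (the
run seeds are `seed + 0..4`). Each iteration fits PLS on a random 80%
calibration subset (mean-centred — the "center" pretreatment) restricted to
the currently retained bands, takes absolute regression coefficients as
weights, and shrinks the retained set to `round(r_i · p)` bands, where
`r_i = a·e^(−k·i)` is fixed by its two endpoint constraints `r_1 = 1` and
`r_N = 2/p`. The shrink is a weighted draw *without* replacement
(probability ∝ |coefficient|): this keeps the adaptive-reweighted character
while making the retained-count sequence exactly follow the schedule from
`p` down to 2 — a with-replacement draw can collapse below two bands by
duplication. Each iteration's retained set is scored by 5-fold RMSECV on
the full training partition; the minimal-RMSECV set wins the run, and the
best of the five runs is returned with its full traces.

**IVISSA** initializes per-band sampling weights at 0.5 and, each round,
draws 1,000 binary inclusion vectors by weighted binary matrix sampling
(band *j* appears in exactly `round(w_j · 1000)` submodels), scores each
submodel by PLS RMSECV, and resets every weight to its frequency among the
best 10% of submodels. Rounds stop when all weights reach 0/1, when the
best submodel's RMSECV has not improved for 3 rounds (the practical
convergence rule — pure frequency updates leave noise-band weights
random-walking near 0.5 indefinitely), or at 50 rounds, in which case the
weight > 0.5 set is returned with a warning. A local stage then widens or
narrows each surviving contiguous interval one band at a time, keeping
changes that lower RMSECV.

**Hybrids** (CARS-SPA, IVISSA-SPA) rerun SPA on the column submatrix of the
parent's selection and map indices back to the original band coordinates,
so the result is always a subset of its parent.

## Classifiers

All tuners use stratified 5-fold cross-validation on the training partition
(one uniform protocol across the five models keeps the comparison fair),
and every stochastic component is seeded.

* **ELM**: random input weights/biases uniform on [−1, 1], sigmoid hidden
  layer, minimum-norm least-squares output weights onto one-hot targets
  (SVD pseudoinverse, so `H > n` merely warns). Hidden sizes 30–100 in
  steps of 10. Inputs are min-max normalised to [−1, 1] with training
  statistics as part of the ELM itself — percent-reflectance inputs
  saturate the sigmoid otherwise.
* **KNN**: features standardized by training mean/sd; K ∈ 5..30; majority
  vote with ties to the smallest class id (deterministic, unlike the usual
  random tie-break).
* **Random forest**: 500 trees (ranger) at each candidate depth 1..20,
  depth by CV, majority vote.
* **PLS-DA**: one-hot response, SIMPLS, components 1..20 (capped below
  `min(n, p)` with a warning), argmax decision.
* **PSO-SVM**: RBF kernel, one-vs-one multiclass (libsvm's native
  reduction), features standardized by training statistics. Particles
  encode `(C, G)` with `C ∈ (0.01, 100]`, `G ∈ (0.01, 10]` and move in
  log10 space — the parameters act multiplicatively, and a linear walk
  wastes the swarm on equivalent large values. Defaults: 20 particles, 50
  iterations, inertia 0.9→0.4 linear, cognitive = social = 2, velocities
  clamped to 20% of the range, positions clamped to bounds.
  Initialization is a Latin hypercube with random initial velocities:
  accuracy landscapes for RBF SVMs are flat over most of the box with a
  narrow viable `G` ridge, and a plain uniform start can strand the whole
  swarm on the plateau.

## Evaluation and the comparison grid

Accuracy is trace/total of the confusion matrix × 100; for every one-vs-rest
collapse this equals the binary `(TP+TN)/(TP+FN+TN+FP)`, which the tests
verify by direct counting. Precision and recall are reported per class;
a never-predicted class yields an absent precision (`NA`) with its counts
alongside, not a silent zero. Because the headline "precision rate" of such
comparisons is ambiguous (macro vs per-class), reports carry both.

`run_grid()` runs every pretreatment × selector × model cell with the shared
split, runs selection on training rows only, tunes on training rows only,
and reports training accuracy from the refit model plus test accuracy and
per-class metrics. The training-only rule is enforced structurally (test
rows are never passed to those stages) and observably: a `stage_observer`
callback receives the exact sample ids entering selection and tuning, and a
dedicated test asserts they never include a test id. Cell failures are
recorded in the result table and do not stop the grid; with an
`output_dir`, finished cells are cached as JSON and reruns resume by cell.

## The synthetic generator

The generator emulates the data a three-stage rapeseed maturity study
produces: 314 bands over 400–1,000 nm, classes of 400/400/700 samples,
class-mean curves that nearly coincide between 420 and 530 nm and diverge
increasingly towards the NIR, and heavy noise outside 420–982 nm (defaults:
edge sd 5%, body sd 1% reflectance, independent Gaussian per band and
sample — the simplest model satisfying the edge-noise structure).

Two requirements pull against each other: class divergence spread smoothly
across the whole NIR would put signal in *every* NIR band (between-class
F ≫ 1 everywhere at n = 1500), which would make "recovering the informative
bands" meaningless for a selector. The generator therefore concentrates all
class separation at eight planted bands (near 750–960 nm) as narrow
triangular features with one-band shoulders, with amplitudes growing
linearly from 4% to 12% reflectance across the sequence — so divergence
still increases with wavelength *along the planted bands*, while off-feature
body bands carry no class signal (F ≈ 1, which the tests check). The green
class sits on the shared sigmoidal base curve, the fully mature class
carries the full feature amplitude, and the yellow class takes an
alternating partial gain (0.65/0.25) across the features. The alternation
matters: with one scalar gain the three class means are collinear, and
one-hot linear-regression classifiers (PLS-DA) then mask the middle class
regardless of separation — distinct per-stage signatures are both the
realistic structure and the one that makes all five classifiers able to
solve the task.

Cube mode inverts the calibration formula exactly (`raw = dark +
reflectance/100 × (white − dark)`, constant references by default), placing
elliptical seeds on a bright plate in a grid layout with round-robin class
assignment, and returns the ground-truth label image, so
calibrate→segment→extract is testable as an identity at zero noise.

What the generator does **not** emulate: scattering/baseline effects that
pretreatments exist to remove (SNV/detrend act as pure transforms here, not
as corrections being validated), wavelength-correlated noise, within-class
biological covariance structure, or realistic seed morphology. Passing
tests therefore demonstrate algorithmic correctness and the expected
qualitative ordering (hybrids smaller than parents, selectors recovering
planted signal), not field performance on real rapeseed spectra — the
published accuracy tables of any real study depend on the instrument data
behind them and are not asserted here.

## Problem sizes used by the tests and the acceptance script

Study-scale checks (split arithmetic, selector recovery, CARS structure)
run at the full default conditions: 1,500 samples × 314 bands, CARS at
1,000 × 5, IVISSA at 1,000 submodels. The five-classifier comparison runs
on a scaled-down replicate of the same structure (classes 150/150/250) with
SPA-selected wavelengths, and the PSO there uses 12 particles × 10
iterations: the swarm converges in a handful of iterations on these
landscapes, and the comparison is about the classifiers, not PSO
endurance. Unit tests use smaller fixtures (tens of samples, ~40 bands)
built by the same generator.

## Known limitations

* IVISSA's global stage can legitimately fail to polarise every weight;
  the returned weight > 0.5 set is then a superset of the signal bands.
  The interval local search only adjusts interval *edges*; it does not
  merge or split intervals.
* SPA's phase-2 evaluator uses a single stratified validation split, not
  repeated CV; with very small training sets its size choice is noisy.
* The ENVI reader handles the band-sequential/interleaved dialects with
  float32/float64 payloads and a wavelength list; it is not a general ENVI
  implementation (no bad-band lists, no map info).
* `confusion_matrix()` requires the full class set to be declared when a
  class can be absent from a partition.
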