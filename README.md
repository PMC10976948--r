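# hyperseed

Chemometrics pipeline for classifying seed maturity stages from
visible/near-infrared hyperspectral images, written for plant-phenotyping
groups who image seed lots (here: oilseed rape at green, yellow and fully
mature stages) and want a tested, reproducible path from raw hypercubes to a
classifier comparison table.

## What it does

The pipeline follows the standard HSI chemometrics workflow:

1. **Reflectance calibration.** Raw sensor counts `I_r` are converted to
   percent reflectance against dark (`I_d`) and white (`I_w`) reference
   cubes: `I_c = (I_r - I_d) / (I_w - I_d) x 100%`.
2. **Seed extraction.** The 440 nm plane (best seed/plate contrast) is
   thresholded with Otsu's method, connected components are labelled, and
   each seed's mean spectrum is extracted; spectra are trimmed to the
   420–982 nm body where edge noise is acceptable.
3. **Pretreatment.** Savitzky–Golay smoothing (SG), first/second
   derivatives (D1st/D2nd), standard normal variate (SNV), polynomial
   detrending, and the combinations SG+D1st, SG+D2nd, SNV+detrend.
4. **Splitting.** Class-stratified Kennard–Stone partitioning at 3:1
   (train:test), the deterministic space-filling rule: first the most
   distant pair, then always the sample farthest from the chosen set.
5. **Wavelength selection.** The successive projections algorithm (SPA),
   competitive adaptive reweighted sampling (CARS, Monte-Carlo PLS runs
   with an exponentially decreasing retained-band schedule from `p` down to
   2), an iterative variable-space shrinkage interval selector (IVISSA,
   weighted binary matrix sampling with elite-frequency weight updates plus
   interval-level local search), and the hybrid chains CARS-SPA and
   IVISSA-SPA.
6. **Classification.** Extreme learning machine (sigmoid hidden layer,
   H ∈ {30, 40, …, 100}), k-nearest neighbours (K ∈ 5..30), random forest
   (500 trees, depth 1..20), PLS-DA (1..20 latent variables) and an RBF SVM
   whose `(C, G)` are tuned by particle swarm optimization with 5-fold
   cross-validated accuracy as fitness. Inner model selection is stratified
   5-fold CV throughout; every stochastic step takes an explicit seed.
7. **Evaluation.** Confusion matrices, overall accuracy
   (`(TP+TN)/(TP+FN+TN+FP)`, i.e. trace/total in the multiclass reading),
   per-class precision/recall, and a `run_grid()` orchestrator that runs
   the full pretreatment × selector × model comparison with one shared
   split and a strict train-only rule for selection and tuning.

A seeded synthetic-data generator reproduces the spectral structure such a
study assumes — 314 bands over 400–1,000 nm, classes of 400/400/700 seeds,
near-coincident class means in 420–530 nm, planted informative NIR bands
with wavelength-increasing separation, heavy edge noise — plus full
hypercube mode (raw/dark/white ENVI cubes with ground-truth masks), so the
whole pipeline is testable without instrument data.

## Worked example

```r
library(hyperseed)

gs    <- generate_spectra(synthetic_spec(seed = 7))
tab   <- trim_wavelengths(gs$table)        # 420-982 nm body
split <- stratified_split(tab)             # class-stratified Kennard-Stone 3:1
split
#> split_result: 1125 train / 375 test ( 3 : 1 )
#>   train test
#> 1   300  100
#> 2   300  100
#> 3   525  175

tr  <- match(split$train_ids, tab$sample_ids)
te  <- match(split$test_ids,  tab$sample_ids)
sel <- select_cars(tab$reflectance[tr, ], tab$labels[tr],
                   wavelengths = tab$wavelengths, n_mc = 200, n_runs = 2,
                   seed = 1)
sel
#> selection_result [cars]: 102 band(s)

fit  <- train_model(tab$reflectance[tr, sel$selected], tab$labels[tr],
                    model_spec("plsda", seed = 1))
rep_ <- eval_report(tab$labels[te],
                    predict(fit, tab$reflectance[te, sel$selected]))
rep_$accuracy
#> [1] 100
```

The split counts are the exact 3:1 stratified arithmetic for classes of
400/400/700; CARS keeps 102 of 293 trimmed bands (the winning iteration of
its shrinkage schedule), and the PLS-DA model classifies every held-out
seed correctly because the planted class separation is large relative to
the body noise.

For the full comparison grid:

```r
cfg <- grid_config(gs$table, chains = c("raw", "d2nd"),
                   selectors = c("full", "cars", "cars-spa"),
                   models = c("elm", "svm"), seed = 1)
res <- run_grid(cfg)
res$table   # chain x selector x model accuracies, feature counts, tuning picks
```

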