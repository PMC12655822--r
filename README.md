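# serscyto

Multiplexed SERS nanotag unmixing and single-cell classification in R.

`serscyto` implements the computational side of a five-plex SERS
(surface-enhanced Raman scattering) cytometry assay, in which breast-cancer
cells are labelled with five spectrally distinct Raman nanotags, each
reporting one integrin surface marker (SiNC → α3, BHQ3 → β1, QXL680 → β3,
QSY21 → β4, DTDC → β5). It is aimed at spectroscopists and analysts who
need a tested, scriptable pipeline from raw single-cell Raman spectra to
cell-line calls:

- **Spectral I/O and preprocessing** — delimited-text spectrum tables on a
  250–3000 cm⁻¹ / 7 cm⁻¹ grid, multi-segment iterative polynomial baseline
  correction, and boxcar smoothing.
- **Classical least-squares (CLS) unmixing** — each measured spectrum is
  modelled as a linear mixture of the pure-nanotag reference spectra,
  `S_total = C₁S₁ + C₂S₂ + C₃S₃ + C₄S₄ + C₅S₅ + Δ`, and the weight factors
  `C₁…C₅` minimising ‖Δ‖₂ are solved per cell (non-negative least squares
  by default, unconstrained least squares optionally).
- **Cell-line classification** — a random-forest classifier on the
  five-marker weight profiles, evaluated with the repeated protocol of 200
  stratified 70/30 train/test resplits, macro-averaged F1
  (`F1 = 2·PRE·REC / (PRE + REC)` per class), confusion matrices, and
  mixed-population prediction summaries.
- **Embedding selection** — a t-SNE perplexity sweep with replicate fits,
  the best replicate per perplexity chosen by the lowest Kullback–Leibler
  divergence and the final perplexity chosen by the lowest Davies–Bouldin
  index.
- **Synthetic data** — a generator for the five reference spectra, designed
  tag mixtures, and three labelled cell-line populations (MM231, MCF7,
  SKBR3) with truncated-normal marker distributions, so the whole pipeline
  is testable without instrument data.

Everything is tidyverse-shaped: functions take data frames first, return
tibbles, chain with the pipe, and fitted objects have `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

```r
library(serscyto)

# Five-reporter reference library on the default axis
lib <- simulate_reference_library()

# A designed 8-mixture panel at 1.5% noise, unmixed by CLS
panel   <- make_mixture_panel(lib, noise_sd = 0.015, seed = 42)
results <- unmix_panel(panel, lib)
recovery_correlation(results)
#> <correlation_result> r = 0.9983, p = 1.37e-48, slope = 0.9932, n = 40
```

The recovered contribution fractions track the designed ones across all 40
(design, tag) pairs with Pearson r ≈ 0.998 — at 1.5% spectral noise the
five tags are essentially fully separable.

```r
# Synthetic three-line population (300 cells per line) and the repeated
# random-forest protocol
cells    <- simulate_cell_population(population_config(), seed = 42)
protocol <- repeat_training(cells, n_iterations = 50, seed = 43)
protocol
#> <training_protocol> 50 iterations, mean macro F1 = 0.9838, mean accuracy = 0.9838

# Retrain on the training split, predict a fresh 450-cell mixture
parts <- split_train_test(cells, seed = 44)
model <- train_forest(parts, seed = 45)
mixed <- simulate_cell_population(population_config(n_per_line = 150),
                                  seed = 46)
pred  <- predict_population(model, mixed)
pred
#> <prediction_summary> 450 cells: MCF7 = 149, MM231 = 142, SKBR3 = 159

profile_correlation(pred, parts[parts$split == "train", ])
#> <correlation_result> r = 0.9995, p = 7.83e-21, slope = 1.0028, n = 15
```

The mean macro-F1 of ~0.98 reflects the overlap the default synthetic
population model deliberately carries between the MM231 and SKBR3 marker
profiles; the predicted per-class mean profiles of the mixed population
agree with the training-class means at r ≈ 0.999 over the 15
(class, marker) pairs.

The full pipeline — references, panel, population, classification,
prediction and embedding selection, with all artifacts written as
delimited text plus a YAML run summary and a seed-stamped log — runs as:

```r
run_pipeline(pipeline_config(), out_dir = "pipeline-output", seed = 1)
```

or from a shell via `inst/scripts/run-pipeline.R`. Every tunable lives in
one YAML-serialisable config; the shipped defaults are in
`inst/extdata/pipeline-config.yaml`.

## Documentation

The methods vignette (`vignettes/sers-cytometry.Rmd`) describes the
mixture model, the baseline-correction and unmixing algorithms, what the
synthetic generator does and does not emulate, the classification and
embedding-selection protocols, and known limitations.
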