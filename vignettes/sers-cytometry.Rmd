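---
title: "Five-plex SERS cytometry: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Five-plex SERS cytometry: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serscyto)
```

## The assay and its linear mixture model

`serscyto` supports a five-plex single-cell SERS assay: gold-nanorod
nanotags carrying one of five Raman reporters (SiNC, BHQ3, QXL680, QSY21,
DTDC) are conjugated to antibodies against the integrins α3, β1, β3, β4
and β5. A cell labelled with all five nanotag colours produces one Raman
spectrum that is, to good approximation, a non-negative linear
superposition of the pure-nanotag spectra:

$$S_\mathrm{total} = C_1 S_1 + C_2 S_2 + C_3 S_3 + C_4 S_4 + C_5 S_5 + \Delta,$$

where $S_i$ is the reference spectrum of nanotag $i$ measured on a pure
solution, $C_i$ is its *weight factor* — the relative signal intensity of
that tag on the cell, a proxy for the targeted integrin's abundance — and
$\Delta$ is the residual. The model assumes (i) additivity of the tag
signals, (ii) a spectrally smooth background that preprocessing removes,
and (iii) reference spectra acquired on the same wavenumber grid as the
cell spectra (or resampled onto it). References are used exactly as
supplied, never re-normalised, so weight factors keep their meaning of
signal intensity relative to the reference acquisition.

Spectra live on a regular Raman-shift axis, by default 250–3000 cm⁻¹ at
7 cm⁻¹ (axis values are bin centers). All spectral containers are plain
tibbles (`wavenumber`, `intensity`, optional `spectrum` id), so every
step chains with the pipe.

## Preprocessing

Two steps precede unmixing.

**Baseline correction** (`baseline_correct()`). The broad SERS continuum
is estimated by *multi-segment iterative polynomial fitting*: the axis is
split into `n_segments` equal-width windows (default 4) sharing one node,
and within each window a degree-`degree` polynomial (default 3) is fitted
repeatedly; after each pass, points lying more than two residual
standard deviations above the current fit are classified as peak points
and dropped from the next fit. This down-weighting-to-zero variant of
the classic modified-polyfit scheme avoids the dip artifact that pure
value-clipping locks in next to strong peaks: excluded peak points exert
no pull, while retained continuum points are fitted at full weight, so
for a smooth true background the fit converges onto it. Iteration stops
after `n_iterations` passes (default 50) or when the fitted baseline
changes by less than 1e-6 in relative norm. Neighbouring segment
baselines are blended linearly over a 3-point overlap so the assembled
baseline has no steps. Corrected intensities are floored at 0 by default
(`floor_zero`), consistent with reading weights as non-negative signal;
the flag exists because residual analysis needs signed values.

On the package's internal benchmark fixture — a linear ramp plus one
Lorentzian peak of amplitude 100 — the residual background error away
from the peak (±3 FWHM excluded) stays below 1% of the peak amplitude,
and a second correction pass changes the peak maximum by well under 5%
(both are asserted in the test suite).

**Boxcar smoothing** (`boxcar_smooth()`). A centered moving average of
odd width `window_points` (default 5 points ≙ 35 cm⁻¹ on the default
grid — no instrument value is published, so the default is a mild,
conventional width). At the edges the window shrinks symmetrically, so
the filter is exactly the identity at width 1 and preserves constants at
every width.

## Classical least-squares unmixing

`cls_unmix()` solves the mixture model per spectrum. Two modes:

- `"nnls"` (default): minimise $\lVert S_\mathrm{total} - \sum_i C_i S_i
  \rVert_2$ subject to $C_i \ge 0$ (Lawson–Hanson active set, via
  `pracma::lsqnonneg`). Non-negativity matches the physical reading of
  the weights as signal fractions, and observed weight factors are
  non-negative throughout. Which variant the original acquisition
  software used is not documented, so the unconstrained solution is kept
  available.
- `"ols"`: the unconstrained least-squares solution by QR; it exists
  chiefly as the analytically checkable oracle (the test suite verifies
  it against the normal equations $(S^\top S)C = S^\top y$ to 1e-9, and
  that NNLS coincides with it whenever it is elementwise non-negative).

No intercept column is included — the baseline is removed in
preprocessing. Degenerate reference libraries are refused rather than
silently pseudo-inverted: a spectral condition number above 1e8 raises
an error naming the most collinear reporter pair. Axis mismatches error
out with a pointer to `resample_to_axis()` (linear interpolation;
points outside the source range become 0 and are counted in the
`n_padded` attribute).

For mixture-design validation, `ratios_to_fractions()` normalises a
ratio design (e.g. 1:6:1:1:1) to theoretical contribution fractions, and
`recovery_correlation()` compares recovered to designed fractions —
recovered weights are renormalised to sum to one within each design
before comparison, because a designed mixture fixes only composition,
not total intensity. Correlations are reported with
`pearson_with_slope_p()`: Pearson's r plus the two-sided t-test p-value
of the regression slope on $n-2$ degrees of freedom.

## The synthetic-data generator

No public single-cell SERS data accompany this assay, so the generator
is a first-class, tested module; it defines the conditions under which
the downstream statistics are computed.

**Reference spectra.** Only the strongest peak position of each reporter
is documented (SiNC 684, BHQ3 1094, QXL680 1140, QSY21 1496, DTDC
510 cm⁻¹). Each default model is a Lorentzian main peak of FWHM 18 cm⁻¹
at the printed shift plus two or three *synthetic* minor peaks (FWHM
14 cm⁻¹, amplitudes 0.15–0.35) at fixed positions chosen not to collide
across reporters. The minor peaks are invented fixtures — unmixing needs
spectrally distinguishable references, and positions beyond the five
printed maxima are not documented truth — and every peak parameter is
overridable through `reporter_models()`.

**Mixtures.** `mix_spectra()` implements the forward model exactly:
weighted sum of references, plus additive Gaussian noise with SD
expressed as a fraction of the library's global peak (default 1.5% for
study-condition runs), plus an optional smooth random cubic baseline.
At zero noise the model is exactly linear in the weights, which the
property tests exploit.

**Cell populations.** Each cell line's five weight factors are drawn
independently from truncated normals on [0, 0.79] — the upper bound
being the largest weight factor observed in the assay — with SD 0.06
and invented means chosen to match the qualitative expression patterns
reported for the three lines: β1 highest in all lines, β4 near zero in
all, β5 clearly elevated in MCF7, and β3/β4/β5 near zero in SKBR3
(MM231: α3 0.45, β1 0.55, β3 0.02, β4 0.05, β5 0.25; MCF7: 0.20, 0.50,
0.15, 0.02, 0.40; SKBR3: 0.30, 0.60, 0.02, 0.02, 0.03). These are
calibration choices, never measured values, and all are overridable in
`population_config()`. Sampling is by rejection; seeds are explicit
function arguments everywhere, and derived child seeds make every
multi-stage procedure reproducible from one top-level seed.

What the generator does **not** emulate: correlated marker expression
within a cell, heavy-tailed single-cell heterogeneity, cell-to-cell
variation in total nanotag load, spectral drift, cosmic-ray spikes, and
non-linear SERS effects at high tag density. Passing tests therefore
demonstrate the correctness of the algorithms under the stated
statistical model, not instrument-grade robustness.

A consequence worth stating plainly: with SD 0.06, the MM231 and SKBR3
mean profiles sit about 0.27 apart in the five-dimensional weight space,
so the two lines overlap irreducibly and even an optimal classifier
misassigns roughly 1% of their cells. The repeated-protocol scores the
acceptance script computes on this population (mean macro-F1 and
held-out accuracy around 0.98) sit at that ceiling; pushing the
synthetic means apart would raise the scores but would abandon the
qualitative calibration above, so the defaults stay put.

## Classification protocol

Features are the five weight factors only — no spectral features leak
into the classifier. The protocol mirrors common practice for this kind
of assay:

1. `split_train_test()`: stratified 70/30 split (proportions preserved
   per class within rounding).
2. `train_forest()`: a 100-tree random forest with unlimited depth (the
   conventional defaults), via the `randomForest` package.
3. `evaluate_classifier()`: confusion matrix as counts and as
   row-normalised fractions (rows = actual), per-class precision and
   recall from the counts, per-class F1 = 2·PRE·REC/(PRE+REC), macro-F1
   as the unweighted mean over classes (classes are balanced by design),
   and accuracy as the trace over the total.
4. `repeat_training()`: the above repeated over `n_iterations`
   independent resplits (default 200), averaging macro-F1 and accuracy.
   "Repeated training" is interpreted as *resplit-and-refit* — the
   reading under which averaging an F1 score across iterations is
   meaningful — and the per-iteration reports and derived seeds are all
   retained.
5. `predict_population()` applies a model retrained on the full training
   split to an unlabelled mixture and reports per-class counts (always
   summing to the number of cells) and per-class mean profiles;
   `profile_correlation()` correlates those mean profiles against the
   training-class means over all 15 (class, marker) pairs.

## Embedding selection

`select_perplexity()` reproduces the two-criterion t-SNE model
selection: for each candidate perplexity (default grid 5, 10, 20, 30,
45, 60, 90, 120, 150, 200, 250, 300 — twelve values spanning 5–300, so
five replicates per value yield a 60-fit sweep), `n_replicates`
embeddings are fitted with distinct derived seeds; the replicate with
the lowest final Kullback–Leibler divergence wins at each perplexity
(ties break to the lowest replicate index); the winning embeddings are
scored with the Davies–Bouldin index against the known training labels,
and the perplexity with the lowest DBI is selected. The full audit trail
is kept.

The t-SNE optimiser is implemented in the package as the exact
O(n²) algorithm (no suitable t-SNE implementation is available among
the package's dependencies, and the population sizes here — hundreds of
cells, five features — do not need Barnes–Hut): per-point binary search
calibrates the Gaussian affinities to the target perplexity; the 2-D
map minimises KL(P‖Q) with a Student-t kernel by gradient descent with
momentum 0.5 → 0.8 at iteration 250, early exaggeration ×12 for the
first 250 iterations, per-coordinate adaptive gains, an automatic
learning rate max(n/48, 50), and small random Gaussian initialisation
(SD 1e-4) so replicates genuinely differ. Affinities and map
probabilities are floored at 1e-12 for numerical safety; the recorded
`kl_divergence` is the final un-exaggerated objective.

The Davies–Bouldin index uses the plain Euclidean definition

$$\mathrm{DBI} = \frac{1}{k}\sum_i \max_{j \ne i}
  \frac{\sigma_i + \sigma_j}{d(c_i, c_j)},$$

with $c_i$ the cluster centroid, $\sigma_i$ the mean member–centroid
distance and $d$ the centroid distance (no variant is documented for
the original analysis, so the standard one is used). Coincident
centroids raise an error rather than returning infinity.

## Pipeline, configuration and reproducibility

`run_pipeline()` chains all stages under one top-level seed and writes:
the reference library, the mixture-panel recovery table, the per-cell
profile table (cell id, label, split, five weights by integrin name,
residual norm), confusion matrices as counts and fractions, the
prediction summary, the embedding audit, a YAML run summary with every
statistic and derived seed, and a timestamped log naming the failing
stage on error. Every tunable lives in `pipeline_config()`, which
round-trips losslessly through YAML (scalar "not set" values are
encoded as YAML nulls via `NA`). Identical config + seed gives
byte-identical output tables, which the test suite asserts.

## Problem sizes and test design

The packaged study conditions are 300 cells per line, 200 protocol
iterations, an 8-design mixture panel at 1.5% noise, and a 450-cell
mixed population; the acceptance script runs all of these as stated.
Unit and property tests use smaller instances chosen for tightness per
assertion — e.g. 100 cells per line for split/report arithmetic, 150
cells and three perplexities for embedding behaviour, 20 label-permuted
protocol iterations for the chance-level null — because the properties
they check (exact arithmetic, determinism, invariances, oracle
agreement) do not sharpen with scale.

## Known limitations

- The reference spectra beyond the five printed peak maxima are
  invented; results that depend on fine spectral overlap structure
  (e.g. exact noise amplification per tag) are generator-specific.
- The classifier protocol assumes balanced classes; macro-F1 remains
  defined but less interpretable under strong imbalance.
- Baseline correction targets broad smooth continua; it is not a cosmic
  ray filter, and sharp baseline steps violate its per-segment
  polynomial assumption.
- The exact t-SNE scales quadratically in cells; beyond a few thousand
  cells a Barnes–Hut implementation would be preferable.
- Weight factors are relative to the reference acquisition; comparing
  them across instruments or sessions requires consistent reference
  measurement.
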