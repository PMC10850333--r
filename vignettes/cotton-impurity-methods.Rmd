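---
title: "Methods: NIR calibration of seed-cotton impurity content"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR calibration of seed-cotton impurity content}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cottonir)
```

## The problem

Machine-picked seed cotton carries plant trash (bracts, leaves, stems) whose
mass fraction — the *impurity content* — drives the price of the crop and
the quality of the downstream lint. Gravimetric determination with a
ginning/analyzer workflow takes tens of minutes per sample. Near-infrared
reflectance spectroscopy offers a rapid proxy: a handheld spectrometer
measures reflectance at 125 channels over 950–1650 nm, and a calibration
model maps each spectrum to the impurity mass fraction (dimensionless, here
roughly 0.03–0.20).

`cottonir` implements the complete calibration workflow:

1. **Pretreatment** — min-max normalization, standard normal variate (SNV),
   or Savitzky–Golay (SG) smoothing.
2. **Sample-set partitioning** — SPXY (joint X–Y distance Kennard–Stone)
   into 180 calibration and 50 prediction samples for the 230-sample design.
3. **Wavelength selection** — successive projections algorithm (SPA) or
   random frog, run on calibration spectra only.
4. **Calibration models** — PLSR, ε-SVR and LSSVM with cross-validated
   hyperparameter search, plus *Cotton-Net*, a small 1-D convolutional
   network fed the full 125-channel spectrum.
5. **Evaluation** — Pearson correlation R and RMSE on both sets
   (R_C/RMSE_C, R_P/RMSE_P), in untransformed mass-fraction units.

A seeded synthetic-spectra generator stands in for the instrument data,
which were never deposited; every stage is therefore testable end to end.

## Pretreatments

*Min-max normalization* rescales each spectrum to [0, 1] via
`(x - min) / (max - min)`. The per-spectrum axis is the default because it
matches SNV's per-spectrum convention; a per-wavelength mode (statistics
fitted on the calibration set, applied to the prediction set) is provided
for completeness. A constant slice is a hard error, not a silent zero.

*SNV* centers each spectrum and scales to unit sample standard deviation
(n − 1 denominator). It is exactly invariant to per-spectrum maps
`x -> a x + c`, `a > 0`, which is why it cancels the multiplicative scatter
and baseline offsets produced by the loose packing of seed cotton.

*SG smoothing* fits a moving least-squares polynomial (default window 11
channels, degree 2 — common chemometric defaults; the source study states
neither). Output values are the fitted polynomial evaluated at the window
center. At the boundaries the window is anchored at the edge rather than
shrunk, and the polynomial is evaluated at the edge channel, so the output
keeps length p and wavelength indexing stays aligned for downstream
selection. The filter is exact on polynomials of degree ≤ the fit degree
and linear in its input.

All pretreatments are stateless per spectrum (no calibration-to-prediction
leakage), except per-wavelength normalization, which fits on the
calibration set only.

## SPXY partitioning

The joint distance is `d(i,j) = dx(i,j)/max(dx) + dy(i,j)/max(dy)`, with
`dx` Euclidean between spectra and `dy = |y_i − y_j|`. Selection is
maximin: seed with the pair at maximum joint distance, then repeatedly add
the sample whose minimum distance to the selected set is largest. Ties
break toward the smallest index, making the split fully deterministic. If
`y` is constant the y-term is defined as 0 and the procedure reduces to
plain Kennard–Stone on the spectral distance. The split runs on raw
spectra by default (configurable), since the study does not say whether
partitioning preceded or followed pretreatment.

## Wavelength selection

**SPA** builds, from every start channel, a chain in which each step
appends the channel with the largest residual norm after projecting out
the span of the already-chosen channels (collinearity reduction). Every
(start, chain-prefix) candidate subset is scored by 5-fold cross-validated
RMSE of a multiple linear regression on the calibration set; the minimum
wins. Folds are assigned round-robin, so SPA is completely deterministic;
ties prefer the smaller subset, then the lexicographically smaller index
tuple. Rank-deficient candidate subsets use the least-squares
pseudo-solution rather than failing.

**Random frog** iterates a stochastic subset search (defaults: 1000
iterations, initial subset of 5 variables, mean-centering inside the inner
model — the study's stated configuration). Each iteration draws a
candidate dimension `Q* = max(1, min(p, round(|N(Q, θQ)|)))`; shrinking
keeps the top `Q*` variables of the current subset by absolute inner-PLS
coefficient, growing adds the top-ranked remaining variables. The
candidate is accepted on inner CV-RMSE improvement, otherwise with
probability `η · RMSE_old / RMSE_new`. The study does not state the
proposal or acceptance rule; `θ = 0.3` and `η = 0.1` follow the original
random-frog literature. The grow-step ranking uses the coefficients of one
inner PLS fit on all p calibration channels, computed once per call — the
most direct deterministic reading of "top remaining variables by absolute
regression coefficient". Selection probabilities are inclusion frequencies
over the accepted subsets; the final subset size is chosen by minimizing
the inner CV-RMSE over probability-ranked prefixes (`final_k = "auto"`),
since the study reports data-dependent counts without a cut rule.

## Calibration models

**PLSR** is NIPALS PLS1 on centered data, 4 latent components by default
(the study's setting). Requesting more components than `min(n − 1, p)` is
an error; exact collinearity below that cap stops extraction early and
silently, as standard PLS implementations do — necessary because perfectly
noiseless spectra are rank-1 in the target.

**ε-SVR** uses the RBF kernel `exp(-γ‖u−v‖²)` and is solved in the dual by
SMO with most-violating-pair selection (no QP library for R is available
in the target environment, and the solver is small). The printed objective
in the source study is a one-sided hinge with no ε-tube, which conflicts
with standard SVR and with the study's own prose; standard ε-SVR is
implemented and the discrepancy documented here. Default `ε = 0.01`
(target units); `C` and `γ` are chosen from logarithmic ladders
`10^-3 … 10^3` by seeded 5-fold CV (ties: smallest `C`, then smallest
`γ`).

**LSSVM** solves the (n+1)×(n+1) KKT system
`[[0, 1ᵀ], [1, Ω + I/γ]][b; α] = [0; y]` with
`Ω_ij = exp(-‖x_i−x_j‖²/(2σ²))`; `γ` and `σ²` come from the same ladders.
Features are standardized inside SVR/LSSVM so kernel widths are comparable
across pretreatments; PLSR centers only.

## Cotton-Net

The network is conv(1→16) → act → conv(16→64) → act → conv(64→48) → act →
average pool → flatten → linear(→1). The source description counts "6
layers" but enumerates five computational stages (3 conv + pool + FC); the
five enumerated stages are implemented. Kernel size 3, stride 1, zero
"same" padding, pool window 2 / stride 2 are package decisions (the study
specifies none of these); they keep the 125-channel signal intact until
pooling and give 15,441 trainable parameters. Initialization pairs with
the activation: LeCun normal for SELU, Kaiming for ReLU, Xavier for
Sigmoid; biases start at zero.

The default loss is the study's printed formula — the natural logarithm of
the mean squared error — stabilized as `log(mse + ε)` with `ε = 1e-8`,
because an exact fit would otherwise give −∞. Because that formula is
*named* MSLE but is not the conventional mean squared logarithmic error,
the conventional form and plain MSE are provided as variants. Note
`log(mse + ε)` is a strictly increasing function of the MSE, so its
minimizers coincide with least squares; its gradient `2r/(n(mse + ε))`
self-normalizes as the fit improves.

Training follows the study configuration: Adam, learning rate 0.001, at
most 200 epochs, batch size 8. There is no early stopping, weight decay or
batch normalization (none are mentioned); the final-epoch weights are the
model, and per-epoch training (and optional validation) losses are
recorded. The implementation is pure R (im2col matrix products), so a
fixed seed yields bit-identical runs; the forward pass is verified in the
test suite against a naive per-position convolution oracle and the
backward pass against finite differences.

Cotton-Net consumes full-spectrum pretreated input; wavelength selectors
apply only to the chemometric models, mirroring the study's asymmetric
design. The ablation grid crosses {SG, Normalization, SNV} with
{SELU, ReLU, Sigmoid} under one shared seed.

## Synthetic data: what it emulates, and what it does not

`generate_dataset()` draws `y ~ U(0.03, 0.20)` and builds

```
clean(wl) = continuum(wl) + Σ_b loading_b · y · exp(-(wl - center_b)² / (2 width_b²))
observed  = a · clean + c + noise,   a ~ N(1, 0.05), c ~ N(0, 0.02), noise ~ N(0, 0.04)
```

on the 125-channel 950–1650 nm grid, 230 samples. Band loadings are
negative (absorption subtracts from the continuum) with defaults centered
at 1210, 1450 and 1550 nm — near cellulose/water/lignin-associated
overtone regions — widths 15–28 nm. The noise regime was calibrated once,
before the acceptance tests were written, so that the best chemometric
pipeline's prediction-set R lands in 0.85–0.95 across seeds — the
difficulty band of the reported application — and has not been revisited.
Channels within two band widths of a band center are returned as ground
truth for selector-recovery tests.

The generator reproduces the *statistical* structure the pipeline assumes
(smooth overlapping bands linear in y, multiplicative scatter, baseline
drift, channel noise). It does not attempt radiative transfer, moisture or
temperature confounders, non-linear band saturation, or instrument
wavelength registration error. A green end-to-end test therefore
establishes that the pipeline machinery is correct and well-conditioned in
that world — not that the study's field performance is reproduced; the
study's table values are out of numeric scope because the underlying
dataset is not public.

## Numerical and design choices

- **Indices are 1-based everywhere**, including JSON artifacts (flagged
  with `index_base: 1`): R-idiomatic; reports also carry wavelengths in nm.
- **Headline R is Pearson correlation.** The printed ratio formula equals
  0 at perfect prediction, so it cannot be the intended statistic; it is
  kept verbatim as the audit function `printed_r_eq5()`.
- Reflectance is the stored quantity throughout; no log(1/R) conversion,
  and targets are never transformed, so all RMSEs are in mass-fraction
  units.
- CSV writes use 17 significant digits, so write/read round trips are
  bit-exact; ragged rows and non-numeric cells fail naming row and column.
- CV folds everywhere are either round-robin (SPA: determinism without an
  RNG) or a seeded shuffle recorded in the artifact (SVR/LSSVM/frog).
- Ties in maximin selection, grid search and subset scoring always break
  toward the smaller index/value, making every stage reproducible.
- Degenerate inputs (constant spectra, zero-variance rows, singular KKT
  systems, rank-deficient subsets) produce located errors or documented
  pseudo-solutions, never silent NaNs.

## Known limitations

- SMO and the grid search are pure R; fitting hundreds of SVR models on
  thousands of samples would warrant a compiled kernel.
- Cotton-Net trains at roughly 0.5 s/epoch (CPU) at the 180×125 design;
  the test suite shortens structure-only training runs accordingly.
- Random frog's proposal/acceptance constants are literature values, not
  fitted; different choices change selection probabilities (though planted
  recovery is robust across them).
- The synthetic world is deliberately simple; comparative statements
  (e.g. network vs. kernel models) on it are recorded per seed by
  `best_model_comparison()`, not asserted as general truths.
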