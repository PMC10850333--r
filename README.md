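# cottonir

Chemometric and convolutional calibration of near-infrared (NIR)
reflectance spectra of machine-picked seed cotton against gravimetric
impurity content (the mass fraction of plant trash, typically 0.03–0.20).

Impurity content sets the price of seed cotton and the quality of the
downstream lint, but the reference gravimetric assay takes 20–30 minutes
per sample. A 125-channel, 950–1650 nm NIR reflectance spectrum can be
acquired in seconds; `cottonir` provides the full modelling workflow that
turns such spectra into impurity predictions:

- **Pretreatment** — min-max normalization `(x − min x)/(max x − min x)`,
  standard normal variate `(x − x̄)/s` (sample sd, n−1), and
  Savitzky–Golay moving least-squares smoothing.
- **SPXY partitioning** — deterministic maximin selection on the joint
  distance `d(i,j) = dx/max dx + dy/max dy` (Euclidean on spectra,
  absolute difference on targets), e.g. 180 calibration / 50 prediction
  samples from a 230-sample design.
- **Wavelength selection** — successive projections algorithm (SPA,
  collinearity-minimizing chains scored by CV-RMSE) and random frog
  (stochastic subset search yielding per-channel selection
  probabilities; defaults 1000 iterations, initial subset 5, centered
  inner PLS).
- **Calibration models** — NIPALS PLSR (4 components), ε-SVR (RBF kernel,
  SMO dual solver) and LSSVM (RBF kernel, KKT linear system), with
  seeded cross-validated hyperparameter ladders.
- **Cotton-Net** — a 1-D CNN (conv 1→16→64→48, SELU/ReLU/Sigmoid, average
  pooling, single linear output; 15,441 parameters) trained with Adam
  (lr 0.001, ≤200 epochs, batch 8) on a log-MSE loss, implemented in pure
  R with bit-reproducible seeded training.
- **Synthetic data** — a seeded generator emulating 230 spectra with
  Gaussian absorption bands linear in the impurity fraction plus
  multiplicative scatter, baseline drift and channel noise, so the whole
  pipeline is testable without the (undeposited) instrument data.

Models are compared by Pearson correlation (R_C/R_P) and RMSE
(RMSE_C/RMSE_P) on the calibration/prediction sets, in untransformed
mass-fraction units.

## Worked example

```r
library(cottonir)

ds <- generate_dataset(synthetic_config(seed = 1))   # 230 x 125 spectra
split <- spxy_split(ds$reflectance, ds$target, 180)  # SPXY 180/50

Xn  <- minmax_normalize(ds$reflectance)              # pretreat
sel <- random_frog_select(Xn[split$train, ], ds$target[split$train],
                          n_iter = 200, seed = 1)    # wavelength selection
fit <- fit_lssvm(Xn[split$train, sel$selected], ds$target[split$train],
                 seed = 1)                           # CV-tuned LSSVM
eval_report(ds$target[split$train],
            predict(fit, Xn[split$train, sel$selected]),
            ds$target[split$test],
            predict(fit, Xn[split$test, sel$selected]))
```

```
R_C=0.9946 RMSE_C=0.0051 | R_P=0.8667 RMSE_P=0.0238 (n=180/50)
```

Read: on the held-out prediction set the model's predictions correlate
0.87 with the true impurity fractions, with a root-mean-square error of
about 2.4 impurity-percentage points expressed as a fraction (0.024) —
the difficulty regime the synthetic generator is calibrated to.

The full experiment grid (3 pretreatments × 2 selectors × 3 models → 18
report rows) and the 9-cell activation ablation of Cotton-Net:

```r
report <- run_grid(ds, grid_config(seed = 1))
abl    <- run_activation_ablation(ds, config = train_config(seed = 1))
best_model_comparison(report, abl)
```

Each stage is also exposed as a file-artifact CLI
(`inst/cli/cottonir`): `simulate`, `preprocess`, `split`, `select`,
`fit`, `evaluate`, `train-net`, `grid`, `ablate`.

## Documentation

See the methods vignette
(`vignettes/cotton-impurity-methods.Rmd`) for the model details, the
synthetic-data contract, numerical choices and known limitations.
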