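# thermospec

Thermal time-constant spectrometry for dynamic infrared thermography: a
regression CNN, trained entirely on synthetic curves, that recovers the
four thermal time constants and amplitudes of a temperature-rise recording,
plus a box-constrained nonlinear least-squares reference fitter.

## The problem

Active thermography cools a patch of skin (a metal block for a few
seconds), then records the surface temperature with an IR camera — 50 Hz
for about six minutes — while the tissue relaxes back. Layered tissue
conducts heat like a Foster ladder of thermal R-C cells, so the
ROI-averaged temperature rise is a sum of saturating exponentials:

    T(t) = Σᵢ Tᵢ (1 − e^(−t/τᵢ)),   i = 1..4

Each cell contributes a time constant τᵢ (seconds) and amplitude Tᵢ (°C).
The spectrum {(τᵢ, Tᵢ)} is a compact signature of the tissue's thermal
dynamics — inflamed skin (e.g., psoriatic plaques) responds with slower,
heavier components than healthy skin — but recovering it from a noisy
sampled curve is a severely ill-conditioned inverse problem.

`thermospec` attacks it with a 9-layer convolutional network mapping a
1024-sample normalized curve to the 8 parameters: dense(1024, sigmoid) →
reshape 32×32 → six conv(32, 3×3, sigmoid) → conv(1, 3×3) → flatten →
dense(8, sigmoid), trained with the weighted loss
`0.2·MSE(τ) + 0.8·MSE(T)` by SGD on synthetic curves whose parameters are
drawn uniformly from [0, 1]. The sigmoid output makes negative time
constants impossible by construction — the classic failure of
unconstrained curve fitting on this problem. A constrained
Levenberg-Marquardt multistart fitter (`fit_least_squares()`) provides the
independent reference: near-exact on clean curves with well-separated
time constants, and bounded to τ > 0 for any input.

## Worked example

```r
library(thermospec)

grid  <- time_grid()                      # 1024 points, dense at early times
train <- build_dataset(3000, grid, seed = 1)
val   <- build_dataset(300,  grid, seed = 2)
test  <- build_dataset(1000, grid, seed = 3)

cfg   <- network_config(learning_rate = 0.05, lr_decay = 0.92,
                        batch_size = 32, seed = 1)
model <- train_network(build_network(cfg), train, val, epochs = 20)

report <- evaluate_model(model, test)
cat(render_report(report))
```

A desk-scale run of the block above (about ten minutes of single-CPU training;
the full reference protocol is 10,000 curves × 5000 epochs) prints:

```
variance   component tau_mse    amp_mse    curve_mse
0          1         0.00738    0.05339    0.00317
           2         0.01811    0.05833
           3         0.02322    0.06327
           4         0.02272    0.06069
           mean      0.01786    0.05892
```

Read: on 1000 held-out clean curves, the mean squared error of the
normalized time constants is ≈ 0.018 (fast components are recovered best),
amplitudes ≈ 0.059, and regenerating each curve from its predicted
spectrum misses the input curve by ≈ 0.0032 mean-square on the [0, 1]
scale. `noise_sweep(model, test)` repeats the evaluation at Gaussian noise
variances 1e-4 … 5e-3 to chart robustness.

Analyzing a measured recording (two-column CSV: time s, temperature °C):

```r
raw <- read_measurement("roi_mean.csv", label = "healthy")
res <- analyze_measurement(raw, model)    # or method = "nls"
res$spectrum        # physical units: tau in seconds, amplitudes in deg C
res$reconstruction_mse
```

`preprocess_measurement()` re-zeroes the recording at its post-cooling
trough, maps it into the unit square, resamples onto the non-uniform grid,
and records the two scale factors; predicted normalized parameters are
multiplied back by them, so physical τ = normalized τ × duration.

A thin CLI wraps the same functions
(`inst/cli/thermospec.R generate | train | evaluate | predict | fit |
analyze`, each with `--seed`).

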