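# t2mese

Quantitative T2 relaxometry for multi-echo spin-echo (MESE) magnitude MRI
of plant tissue at low field — for anyone who needs to turn a stack of
echo images into per-structure water-state parameters: relaxation times,
amplitudes, and bound / semi-bound / free water fractions.

Low-field MESE data are noisy, and the noise is Rician: zero-mean Gaussian
noise on both quadrature channels becomes a signal-dependent, biased
magnitude distribution after reconstruction, with SNR falling echo by echo
along the train. The package provides the full chain for that setting:

* **Forward simulation** — multi-exponential decay phantoms
  (`S(t) = Σ_j A_j e^{-t/T2_j}`), including a three-ring reference object
  (A = 250; T2 = 80/200/600 ms) and a six-structure tomato-like template,
  with channel-level Rician noise injection and per-echo SNR estimation
  from background Rayleigh statistics.
* **3D non-local-means denoising** — patch similarity computed across the
  echo dimension with an echo-dependent bandwidth `h(te)` driven by the
  measured per-layer noise power, against a layer-wise 2D baseline.
* **Swarm inversion** — mono- to quad-exponential fits by chaotic immune
  particle swarm optimization with adaptive component-interval bounds:
  logistic-map coefficient updates, clonal selection with hypermutation,
  crossover and receptor correction (conditional linear solve of the
  amplitudes), and periodic compression of each parameter's search
  interval around the incumbent best. Components are reported in
  ascending-T2 order with the water-state labels T21/T22/T23 and
  normalized proportions.
* **Structure analysis** — Rician-bias-corrected region-mean curves with
  per-echo standard errors, robust echo exclusion, R²/RMSE before and
  after exclusion, and voxel-wise T2/amplitude mapping.

## Worked example

Simulate the reference phantom at the tomato protocol (61 echoes, 30 ms
spacing), add Rician noise, and invert the inner ring's mean decay:

```r
library(t2mese)

te      <- mese_te_grid(61)                       # 30, 60, ..., 1830 ms
phantom <- generate_phantom(phantom_rings(),
                            acquisition_params(te_grid = te))
noisy   <- add_rician_noise(phantom$stack, sigma = 10, seed = 1)
noisy
#> <mese_stack> 256 x 256 x 61 echoes, TE 30..1830 ms, sigma = 10

curves <- extract_region_curves(noisy, phantom$labels)
curves$region_1
#> <decay_curve> 61 echoes, TE 30..1830 ms, y[1] = 171.816, sigma = per-echo (0.162..0.928)

invert_decay(curves$region_1, e = 1, config = optimizer_config(seed = 1))
#> <fit_result> e = 1, criterion = 122.9, R2 = 0.9971, RMSE = 0.00907, 134 iterations
#>             A      T2
#> [1,] 249.8378 80.0913
```

The inner ring was simulated with A = 250 and T2 = 80 ms; the fit recovers
249.84 and 80.09 from the noisy stack. `y[1] = 171.816` is the
bias-corrected first-echo region mean (`250·e^{-30/80} = 171.82`), and the
per-echo sigma is the standard error of the corrected region mean, which
weights the least-squares criterion. R² and RMSE are computed on
first-echo-normalized signals.

Per-echo SNR falls monotonically along the train, the core difficulty this
pipeline addresses:

```r
head(estimate_layer_snr(noisy, phantom$labels > 0, phantom$labels == 0), 3)
#>   te signal_power noise_power sigma_hat    snr
#> 1 30     50332.65      100.62     10.03 500.24
#> 2 60     41646.94      101.30     10.06 411.14
#> 3 90     35118.22      101.26     10.06 346.82
```

`run_pipeline(pipeline_config(...))` chains the whole thing — simulate,
noise, denoise, extract, exclude, invert, report — into a run directory
with provenance sidecars; `inst/cli/mese-relaxo` exposes each stage as a
shell command.

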