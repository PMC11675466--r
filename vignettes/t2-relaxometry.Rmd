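---
title: "Multi-echo T2 relaxometry: models, denoising, and swarm inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-echo T2 relaxometry: models, denoising, and swarm inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2mese)
```

## The measurement and the signal model

A multi-echo spin-echo (MESE) acquisition samples the transverse-relaxation
decay of every voxel: one magnitude image per echo time TE, at a fixed echo
spacing. With a long repetition time (TR = 4000 ms here, much larger than
tissue T1), the longitudinal magnetization recovers essentially completely
between excitations, so the voxel signal is proportional to proton density
times the T2 decay alone. `long_tr_factor(4000, t1)` quantifies the
approximation: the recovery factor is at least 0.98 for T1 up to 1000 ms,
which covers plant tissue at low field.

Each voxel (or region-mean) signal is modelled as a discrete sum of
exponential components,

$$S(t) = \sum_{j=1}^{e} A_j \, e^{-t / T2_j},$$

with `e` between 1 and 4. In fruit tissue the tri-exponential reading is the
established one: the shortest-T2 component (labelled T21) is bound water,
the middle (T22) semi-bound water, and the longest (T23) free water;
amplitudes normalized to sum to one give the relative content of each state.
`simulate_decay()` evaluates the model, `classify_components()` applies the
labelling after a fit.

Fitting minimizes the weighted least-squares criterion

$$C(\theta) = \sum_t \frac{(y_t - S(\theta, t))^2}{2\sigma_t^2},$$

where `sigma` is either a single noise scale (ordinary least squares up to a
constant) or a per-echo vector. The per-echo form matters: region-mean
curves extracted from magnitude images are strongly heteroscedastic along
the echo train (see below), and unweighted fits of a tri-exponential mixture
amplify the late-echo noise into tens of percent of error on the middle
component.

## The synthetic phantom and what it does (and does not) emulate

`phantom_rings()` builds the reference simulation object: three concentric
rings on a 256×256 grid, amplitude 250 everywhere, mono-exponential T2 of
80, 200 and 600 ms from inner to outer, zero background — a geometry whose
region decays are known exactly, on the standard 30 ms echo grid. The ring
radii are not uniquely determined by the source figure; the default uses
equal radial thickness spanning 80% of the grid half-width. Since region
fits consume region means, the exact layout is irrelevant to inversion
correctness; `equal_area = TRUE` instead places radii at $R\sqrt{k/n}$ so
the three rings have equal areas and the foreground mean is an exact
equal-amplitude three-component mixture — the canonical hard test case for
multi-exponential inversion. `phantom_tomato()` provides a six-structure
label-map template (exocarp, endocarp, partition, ovary tissue, seeds,
placenta) with plausible tri-exponential mixes, purely as a geometric
stand-in for a segmented fruit section.

Noise is injected the way magnitude MRI noise arises: independent zero-mean
Gaussian noise of standard deviation `sigma` on the real and imaginary
channels, then magnitude reconstruction, `sqrt((S + n1)^2 + n2^2)`
(`add_rician_noise()`). Background voxels therefore follow a Rayleigh
distribution with mean `sigma * sqrt(pi/2)`, and low-SNR voxels acquire the
well-known Rician floor. The generator is white across space and echoes and
simulates no k-space effects, coil sensitivity profiles, motion, or
T1-weighting — so passing tests demonstrate correctness of the estimation
chain under the stated noise model, not robustness to structured scanner
artefacts.

`estimate_layer_snr()` estimates per-echo signal power (mean squared
intensity over a signal mask) and noise power via the Rayleigh-corrected
background statistic $\hat\sigma^2 = \mathrm{mean}(v_{bg}^2)/2$. On the
constant-sigma noisy phantom the resulting SNR decreases strictly along the
echo train, the defining difficulty of late-echo relaxometry.

## Rician bias and region-mean extraction

Averaging magnitudes over a region reduces random error but not the Rician
bias, which at late echoes masquerades as a slow decay component and biases
every fitted T2 upward. `extract_region_curves()` therefore corrects by the
exact second moment of the Rice distribution, $E[v^2] = S^2 + 2\sigma^2$,
estimating the region signal as the *signed* square root of
$\mathrm{mean}(v^2) - 2\sigma^2$. Two numerical choices matter here:

* the **signed** root: where the true signal is ≈0, the estimate of $S^2$
  fluctuates around zero, and rectifying at zero before the square root
  would re-introduce a spurious positive tail — precisely the artefact the
  correction is meant to remove;
* the **per-echo standard error** attached to the curve: the delta-method
  SE of the signed-root estimator, floored where the estimate is within its
  own noise of zero. This is what makes the downstream weighted fit
  statistically sane at late echoes.

The correction is exact for homogeneous regions (every labelled phantom
region, and approximately each segmented tissue structure); for
deliberately mixed regions the package averages per-label corrected curves
rather than applying the second moment to the mixture, because the mixture
second moment estimates an RMS, not a mean. `correct_rician_bias()` offers
the cruder single-curve version for voxel work. The denoiser applies no
bias correction of its own.

## 3D non-local means across the echo dimension

`nlmeans3d()` denoises by weighted averaging over each voxel's spatial
search window; the weight of a candidate derives from the distance between
3D patches that extend along the echo axis. Because the decay ties adjacent
echoes of a voxel together strongly, the echo-extended patches discriminate
structure from noise far better than single-layer patches, especially at
the late, low-SNR echoes. The patch distance is a separable-Gaussian-kernel
weighted mean of squared differences: kernel sd `a2` (default 2 voxels) on
the two spatial offsets, `a1` (default 1 echo) on the echo offset; patches
are clipped at borders with the kernel renormalized over offsets valid for
both patches.

Weights use the noise-compensated form

$$w = \exp\!\left(-\frac{\max(d - 2\sigma^2(te),\, 0)}{h(te)^2}\right),$$

because $2\sigma^2$ is exactly the expected distance between two noise
realizations of identical structure: subtracting it makes same-structure
candidates score weight ≈1, leaving `h` to control pure edge tolerance.
With a zero noise-power schedule the form reduces to the plain exponential
weighting. The self weight is set to the maximum candidate weight (raw
self-distance zero would dominate and suppress denoising), and weights are
normalized to sum to one.

The bandwidth schedule `h(te)` comes from the measured per-layer noise
power (`h_schedule_from_noise()`, default `h = sigma_hat(te)` made
non-decreasing by a running maximum with a small positive floor), so
smoothing strengthens along the echo train as the SNR falls. Defaults:
patch radius 2 (space) and 1 (echo), search radius 5. `nlmeans2d()` is the
layer-wise baseline; with echo patch radius 0 and shared schedules the 3D
filter reproduces it exactly, which is tested. `evaluate_denoising()`
reports PSNR/RMSE/SSIM against the noiseless truth.

## The swarm inversion engine

`invert_decay()` minimizes the criterion with a particle swarm refined by
three mechanisms, all operating inside per-component interval bounds
(`component_bounds`): the e relaxation-time intervals are non-overlapping
and ascending, which both encodes the physical water-state segmentation and
resolves the label-switching degeneracy of multi-exponential fits. Defaults
for e = 3 are (1, 100], (100, 400], (400, 2000] ms. Amplitude intervals are
`[0, 2 y_1 f_j]` where $f_j = \min(e^{TE_1/T2^{lo}_j}, e^2)$ undoes the
decay a slow-end component has already suffered by the first echo — without
this back-extrapolation the true amplitude of a fast component (T2 below
~45 ms at TE₁ = 30 ms) can lie outside the naive `[0, 2 y_1]` interval.

1. **Chaotic coefficients.** The stochastic coefficients r1, r2 of the
   velocity update evolve by the logistic map at full chaos,
   `r' = 4 r (1 - r)` (`chaos_step()`), rather than fresh uniform draws.
   The map's absorbing set needs care: inputs outside (0, 1) and the fixed
   point 0.75 are reseeded uniformly (0.5 maps to 1, which reseeds on the
   next step; 0.25 maps onto the fixed point).
2. **Immune operators** (`immune_operators()`). The highest-affinity tenth
   of the swarm (affinity `1/(1 + fitness)`) is cloned three times. Clones
   undergo (a) hypermutation — Gaussian jitter at the swarm's current
   per-dimension spread, the clonal-selection local search that lets the
   algorithm refine once the swarm contracts; (b) chaotic full-range
   mutation per dimension with probability 0.1 — the exploration move;
   (c) arithmetic crossover between random clone pairs with probability
   0.5; and (d) receptor correction — each clone's amplitudes are snapped
   to their conditional least-squares optimum given its relaxation times
   (the criterion is linear in the amplitudes, so this is an exact,
   bounded-cost solve). Survivor selection over parents and clones is
   elitist: the best criterion value never worsens, and the swarm size is
   preserved. Receptor correction is what makes the tri-exponential problem
   tractable: it reduces the effective search to the e relaxation times.
3. **Adaptive interval compression** (`adapt_bounds()`, every 10
   iterations). For each dimension with incumbent best `g` inside
   `[lo, hi]` of width `W`, let `m1 = (hi - g)/W`; when `s < m1 < 1` the
   upper bound moves toward `g` by `|ln m1|/gamma` of the width
   (symmetrically for the lower bound), with `s = 0.6`, `gamma = 5`. The
   incumbent always remains strictly inside, adjacent relaxation-time
   intervals are clipped at the midpoint of any would-be overlap, and a
   dimension whose incumbent sits on a bound is left untouched. The rule
   only compresses — by at most `|ln s|/gamma` ≈ 10% of the width per
   application — so early mis-convergence cannot slam the window shut.

The iteration budget defaults to 500 per exponential component (150 for the
`"fast"` preset used in voxel-wise mapping and provisional fits), with a
stall rule (no relative improvement of 1e-10 over 50 + 50e iterations) and
an inertia weight decaying linearly 0.9 → 0.4. All randomness flows from
the config's `seed`, restoring the caller's RNG state afterwards; the same
curve and seed reproduce the fit bit for bit.

On noiseless mono-exponential curves the engine agrees with the log-linear
regression oracle to better than 0.1% relative error, and on the noiseless
tri-exponential phantom mixture with a Levenberg–Marquardt oracle started
at the truth to within 5% (in practice, machine precision); those
gradient-based fitters remain test oracles only, as their sensitivity to
initialization is the problem the swarm exists to avoid.

## Echo exclusion

Isolated corrupted echoes (interference spikes) are removed before the
final fit by `exclude_echoes()`: fit a provisional model, standardize
residuals by the per-echo noise scale and the median absolute deviation,
and drop echoes beyond `k = 3` robust standard deviations — never more than
20% of the train, and never below the `2e + 2` echoes the model order
needs (the call then refuses and flags it). One subtlety: a gross outlier
skews the provisional least-squares fit enough to push clean echoes over
the threshold, so when anything is flagged the provisional model is refit
once without the single worst echo before the final flagging pass. Fit
quality is reported before and after exclusion as R² and RMSE
(`fit_metrics()`), computed on signals normalized by the measured
first-echo value so RMSE lives on a comparable ~0–1 scale across regions.

## From stacks to tables and maps

`extract_region_curves()` → `invert_structures()` produces the
per-structure table (mono- and tri-exponential, raw and post-exclusion
metrics, classified components and proportions); `voxelwise_maps()` fits
each masked voxel independently (mono-exponential by default, with a stride
option — tri-exponential per voxel at 256² is beyond desk scale at default
swarm settings) and assembles T2 and amplitude maps with `NA` sentinels for
masked-out or failed voxels. `run_pipeline()` chains simulation, noise,
denoising (bandwidths from the measured per-layer noise), extraction,
exclusion, inversion and reporting, stamping every run with its effective
configuration and an MD5 config hash.

## Problem sizes, tolerances, degenerate inputs

* Unit tests run on 32–64 px phantoms with 10–45 echoes; the end-to-end
  checks use the full 256×256 phantom (61 echoes for recovery, 45 for the
  SNR profile) and 128×128×45 for the denoising comparison, with
  voxel-wise fits on a stride-4 subsample. These sizes were chosen so the
  whole suite completes in a few minutes while exercising the
  acquisition-scale geometry.
* Noise fixtures: sigma = 10 for the denoising and SNR studies (first-echo
  ring SNR ≈ 17–24, the low-SNR regime the method targets); the mixture
  recovery study sets sigma from a first-echo SNR of 50 on the foreground
  mean.
* Constant signals make R² undefined (reported `NA`); zero total amplitude
  makes proportions undefined (an error); a zero noise floor in the
  bandwidth schedule is replaced by a small positive epsilon; curves whose
  first echo is nonpositive are skipped in voxel maps.
* The equality `PSNR = Inf` flags a perfect reconstruction in
  `evaluate_denoising()`.

## Known limitations

* The label map is an input: no segmentation is shipped. Every downstream
  computation is independent of how the map was produced.
* The Rician second-moment correction assumes homogeneous regions and a
  known (or well-estimated) channel sigma; voxel-level fits on raw noisy
  stacks retain the magnitude floor bias unless `correct_rician_bias()` is
  applied, and median voxel T2 in a noisy ring accordingly sits a few
  percent above the region-fit value.
* Discrete components only: no inverse-Laplace / NNLS continuous T2
  spectra.
* The tri-exponential problem remains ill-conditioned near merging
  components; the non-overlapping interval defaults encode the prior that
  the water states are separated by factors of ~2.5 or more, and should be
  re-set per tissue when that prior fails.
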