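---
title: "Simulating and analyzing fluctuation-based super-resolution data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing fluctuation-based super-resolution data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sofisim)
```

# Scope and intended use

`sofisim` simulates image sequences of stochastically blinking fluorophores
under a parameterized microscope/camera model and analyzes them with
cross-cumulant SOFI (orders 2–7), the balanced-SOFI post-processing chain,
and a basic single-molecule localization (STORM) pipeline. Its purpose is
*qualitative, desk-scale comparison* of acquisition conditions — labeling
density, photoswitching kinetics, photon budget, camera type, frame count —
before committing microscope time. It is not a rigorous optical simulator:
the PSF is a 2-D Gaussian, the sample is planar, and photophysics is
two-state.

# The forward model

## Emitter placement

Emitters live in continuous pixel coordinates, origin at the center of
pixel (0, 0), so pixel `(i, j)` covers `[i − ½, i + ½] × [j − ½, j + ½]` —
this makes the `(x − x̂ ± ½)` terms of the pixel-integrated PSF exact pixel
boundaries. Three patterns are built in: uniform random fields (Poisson
count with mean density × area, matching random labeling; a `fixed_count`
override exists for reproducible examples), user-supplied point lists (for
two-point resolution tests), and filaments (a Poisson process on a
piecewise-linear curve at a linear density per µm, equivalent to
exponential arc-length gaps). Filament labeling jitter defaults to 0
(on-curve) since nothing in the modelled chemistry pins a value; it is
user-settable.

## Photophysics

Each emitter follows an independent two-state continuous-time Markov
process with exponential dwell times of means `tau_on` and `tau_off`
(seconds). The key dimensionless parameter is the on-time ratio
`rho_on = tau_on / tau_off`; photoswitchable fluorescent proteins sit
around 0.1, organic dyes below 0.01. All emitters share one parameter set —
sample-dependent spatial variation of kinetics is real but uncontrollable,
and is deliberately out of scope.

Two modelling decisions deserve note:

* **Frame integration.** The state trace is integrated exactly over each
  exposure window, so a switch mid-frame produces a fractional emissive
  value. This is physically faithful for cameras; a `binary_sampling`
  option samples the state at mid-exposure instead for comparison with
  idealized treatments.
* **Bleaching clock.** Overall bleaching (switching fatigue plus classical
  excited-state bleaching) is an exponential clock of mean `t_bleach`
  running in *wall time* from t = 0. Under the constant illumination
  typical of fluctuation imaging, excitation and switching are
  proportional, so a wall-time clock reproduces the observed exponential
  fade of mean fluorescence; whether the clock should instead count only
  emissive time is unknowable from the modelled data, and wall time was
  chosen once. `fit_bleach_decay()` recovers the constant from the
  mean-fluorescence curve (tested to 10% at 2000 emitters × 500 frames).

The initial state is drawn from the stationary distribution
`p_on = tau_on/(tau_on + tau_off)`, so simulated traces have no
equilibration transient (real measurements may).

## Optics and camera

The PSF is a symmetric 2-D Gaussian with standard deviation
`sigma = 0.21·lambda/NA` (the standard widefield Gaussian approximation;
the proportionality constant is a convention, and `psf_sigma_px` can be set
directly). An emitter's contribution to a pixel is the product of 1-D
Gaussian masses integrated over the pixel extent (erf differences),
evaluated for pixels within 3σ of the emitter. That truncation loses the
2-D Gaussian tail mass `exp(−9/2) ≈ 1.1%` — a documented bias, negligible
for cumulant shapes but visible if you count photons to better than 1%.
The containing pixel is always part of the support, so the σ → 0 limit
degenerates cleanly to a single pixel.

The camera chain, per pixel and frame with expected photon count λ:

1. photons registered `n ~ Poisson(λ · QE)`;
2. EMCCD mode: amplified charge `~ Gamma(shape = n, scale = gain)`, with
   zero charge when `n = 0` (no photoelectron, nothing to amplify);
   sCMOS mode (`em_gain = FALSE`): deterministic `n · gain`;
3. Gaussian dark/readout noise of standard deviation `dark_noise_sd`, then
   the constant baseline, clipping at 0, and optional integer quantization.

The compound law has mean `λ·QE·gain + baseline` and variance
`2·λ·QE·gain² + dark²` (EMCCD; the factor 2 is the excess noise of the
stochastic gain), which the test suite verifies against Monte-Carlo moments
at 10⁵ pixels. The Gaussian noise is added after the baseline and before
clipping; the ordering is a convention and only matters within a few dark
noise SDs of zero.

# Cumulant analysis

## Estimator

`joint_cumulant()` implements the moments-to-cumulants expansion over set
partitions, `kappa = Σ_P (−1)^{|P|−1}(|P|−1)! Π_{B∈P} E[Π_{i∈B} X_i]`, on
mean-subtracted series, so partitions with singleton blocks vanish and only
1, 1, 4, 11, 41, 162 partitions survive for orders 2–7. The expansion is an
exact polynomial identity in the empirical moments, hence exactly shift
invariant: constant offsets (stationary background) cancel to rounding
error, which the suite asserts at 10⁻⁸ after adding 10⁴ to every pixel.
Order 2 reduces to the sample covariance (cross-correlation of centered
traces). Zero time lag is the default; nonnegative per-member lags are
supported and reduce noise correlation at order 2–4 if wanted.

## Virtual pixels and distance weights

For order n and up-sampling factor f (default f = n; f must divide n so
the geometry works out), the virtual node at fractional offset
`(a/f, b/f)` is assigned n member pixels with 0/1 integer offsets whose
mean is exactly the node — `n·a/f` members shifted in x and `n·b/f` in y,
assigned lexicographically. Among integer multisets with the required sum
this minimizes the spread (values confined to {0, 1}), and because the
pairwise-distance sum depends only on the x and y multisets separately, the
lexicographic overlap is as good as any pairing — the choice is
deterministic and documented rather than optimized per node.

Spreading members attenuates the cross-cumulant of a Gaussian PSF by
`exp(−Σ_{i<j}|r_i−r_j|²/(2nσ²))` (from `Σ_i(r_i−r̄)² =
(1/n)Σ_{i<j}d_ij²`), so each virtual pixel is multiplied by the reciprocal
weight. The weight uses the *physical* PSF width; because the rendered PSF
is the Gaussian convolved with the pixel box, a small residual mismatch
survives, which is exactly why flattening is empirical (below).

The image engine exploits the fact that member pixels only take 0/1
offsets: across all f² combinations of an order, block moments reduce to a
few hundred distinct "compositions" (multisets of shifted-trace powers)
that are computed once per statistical block, chunked over frames for
memory, and reused by every combination and partition. Virtual pixels on
the high-index border, where no combination fits, are zero and flagged in
`border_mask`.

Traces are mean-subtracted per statistical block (`batch_frames`; default
one block for the whole stack) and block estimates averaged — useful when
bleaching makes traces non-stationary.

## Balanced-SOFI post-processing

* **Flattening** rescales each of the f² interleaved sub-grids so its mean
  absolute value matches the cross-subgrid average. This removes the
  periodic checkerboard left by imperfect distance weights (e.g. a
  misestimated σ). Gains are positive — no sign changes — and an all-zero
  image passes through unchanged. Gains are global per sub-grid; a local
  windowed variant was considered and rejected as it can chase real
  structure.
* **Deconvolution** is Richardson–Lucy with a Gaussian kernel of width
  `σ·f/√n` on the virtual grid (the order-n cumulant PSF), default 10
  iterations, exposed because more iterations sharpen but ring — at
  sufficiently high SNR (around 20 dB) the artifacts are negligible. RL is
  multiplicative, so negative values (legitimate in raw odd-order
  cumulants) are clipped to zero on entry; they survive flattening
  untouched and are simply not restored afterwards. This is a documented
  limitation of the multiplicative algorithm.
* **Linearization** takes `|value|^(1/n)` pixelwise, undoing the `eps^n`
  brightness response so one bright emitter no longer swamps its dim
  neighbors. The output is nonnegative by construction.

Raw order-n spots of an isolated emitter narrow as `σ/√n` (verified to 3%
for n = 2, 3, 4 at high SNR); deconvolution narrows further toward the
full n-fold gain but the suite asserts only strict monotone narrowing, not
an exact factor, since the limit depends on iteration count and SNR.

Two practical caveats established while testing: pixel integration
inflates the effective PSF width by `sqrt(1 + 1/(12σ²))` (1% at σ = 2 px,
2.5% at σ = 1.3 px), and camera shot noise contributes to auto-cumulant
members, broadening cumulant spots by several percent at low SNR — width
measurements should be made on bright, unit-gain acquisitions.

# The STORM pipeline

Detection runs per frame on a negated, zero-sum Laplacian-of-Gaussian
filtered image (constants and linear background trends vanish exactly;
blobs become positive peaks). The threshold is expressed in robust
(median-absolute-deviation) noise SDs of the filtered frame — the field
quotes thresholds this way because the raw digital scale is camera
dependent; the default of 5 SDs gives well under 0.1 false positives per
64×64 frame. Connected regions above threshold become square windows
centered on the region peak; windows whose peaks are closer than
`min_separation_px` are *both* dropped — this basic pipeline is a
sparse-regime algorithm, and guessing at overlapping emitters produces
worse artifacts than discarding them.

Fitting is an unweighted least-squares Levenberg–Marquardt fit on the *raw*
data (the filtered image is only for detection) of a symmetric
pixel-integrated Gaussian plus constant offset, initialized at the
intensity centroid of the background-subtracted window. The
pixel-integrated (erf) model was chosen over a sampled Gaussian because it
matches how the camera integrates the PSF: noiseless windows are then
recovered to < 10⁻³ px in position and width, whereas the sampled model
carries an irreducible ~2.5% width bias at σ = 1.3 px that would leak into
the width filter. Note the unweighted estimator (the standard choice for
this basic pipeline) is ~√2 less efficient in RMSE than a weighted fit;
the suite verifies the `1/√N` photon scaling and this constant's range.

Fits are screened on width (± 50% of the expected σ by default) and on
amplitude (default lower bound 2× the frame noise SD); the thresholds are
exposed because "deviating significantly" is application dependent.
Rejection reasons are recorded, and the rules are idempotent and
order-independent. Rendering is a 2-D histogram of accepted localizations
on an up-sampled grid, optionally Gaussian-blurred (0.5 up-sampled px is a
common display choice; the default is the pure histogram, which conserves
counts).

# Quality metrics

`estimate_snr_sb()` works on the temporal-average image: signal/background
masks come from Ridler–Calvard iterative threshold selection (midpoint
iteration to 10⁻⁶ of the range), `I_peak` is the maximum of the average
image, `B` the background-mask mean, `S/B = (I_peak − B)/B`, and
`SNR = 20·log₁₀((I_peak − B)/σ_noise)` with σ_noise the pooled temporal SD
over background pixels. The dB convention (20·log₁₀ of an amplitude ratio)
is this package's documented choice; quoted dB figures for the presets are
defined under it. `estimate_on_time_ratio()` uses ground-truth traces when
available (total on-time over total off-time; recovers generator settings
of 0.02–0.2 within 10% at 10⁴ frames) and otherwise thresholds the most
strongly fluctuating pixel traces at their two-level midpoint — a rough
estimate that assumes resolvable single-emitter pixels. `measure_fwhm()`
interpolates a line profile bilinearly and reports the linear-interpolated
full width at half of (peak − profile minimum); it is affine invariant.

# Scenario presets and problem sizes

Five configuration files ship under `inst/presets/`, all 64×64 px at
100 nm/px, NA 1.2, λ 520 nm (σ ≈ 0.91 px), EMCCD (QE 0.7, gain 30, dark
noise 2 DU, baseline 100 DU, 10 ms frames), background 10 photons:

| preset | deviation from standard |
| --- | --- |
| `standard` | filament at 150/µm, 500 photons/frame, ρ_on = 0.1, 1500 frames |
| `short_acquisition` | 600 frames |
| `short_off_state` | τ_off = 10 ms, on the order of the frame time |
| `low_snr` | 40 photons/frame (≈ 8 dB under the SNR convention above) |
| `high_density` | uniform 1000 emitters/µm² over the central 2×2 µm, 1000 frames |

Frame counts are desk-scale choices made once: 600 and 1000 frames are the
canonical "short acquisition" figures for this kind of comparison; 1500
frames keeps a full orders-2–7 bSOFI + STORM run around a minute. The test
suite runs every preset end-to-end.

The synthetic generator emulates stationary blinking statistics, spatially
uniform kinetics, a planar sample, and a shift-invariant Gaussian PSF. It
does **not** emulate dipole orientation effects, 3-D defocus, sCMOS
pixel-dependent gain maps, multi-dark-state kinetics, or power-dependent
switching — so passing tests demonstrate correctness of the estimators and
pipelines under the stated model, not performance on arbitrary real data.

# Numerical choices and degenerate inputs

* All randomness flows from one integer seed through a documented affine
  splitting scheme (`split_seed(seed, stream)`), so every stage is
  independently reproducible and CLI runs are byte-identical per seed.
* Cumulant orders outside 2–7 error; stacks under 100 frames warn.
* `flatten` of an all-zero image, RL on a flat image (a fixed point), and
  empty localization tables (zero image plus warning) are all defined.
* 16-bit TIFF stacks round-trip integer digital units bit-exactly; 32-bit
  stacks are stored on the TIFF backend's fixed-point grid with a
  power-of-two scale in a YAML sidecar, i.e. a relative precision of 2⁻³²
  of full scale.
* Gamma shape 0 (no photoelectrons) yields exactly zero charge; clipping
  at 0 happens once, after dark noise and baseline.

# Known limitations

The cumulant estimator is the plain moment-expansion plug-in, adequate for
imaging but biased at O(1/T); k-statistics would be unbiased but do not
generalize cleanly to the batched, lagged cross-pixel setting. Negative
cumulant values do not survive deconvolution. The STORM pipeline neither
fits multiple emitters per window nor corrects drift. The bSOFI parameter
maps (molecular density, brightness and blinking-rate estimation from
combining orders) are a possible extension; only linearized images are
produced here.
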