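---
title: "Measuring capillary oxygen with gated phosphorescence lifetimes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring capillary oxygen with gated phosphorescence lifetimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

Two-photon phosphorescence lifetime microscopy (2PLM) measures oxygen
partial pressure (Po2) by exciting a phosphorescent sensor (PtP-C343) at a
point inside a capillary and timing the decay of its emission: molecular
oxygen quenches the triplet state, so higher Po2 means a shorter lifetime.
The acquisition is gated — an acousto-optic modulator opens for 25 µs
(fluorescence, used to see passing red blood cells, which exclude the
plasma dye and darken the signal) and closes for 225 µs while binned photon
counts trace the phosphorescence decay, repeating every 250 µs at a
1.25 MHz sampling clock (0.8 µs bins). Because single decays carry only a
few photons, tens of thousands of cycles are pooled before a lifetime is
fitted.

Po2 inside a capillary is not constant: each passing erythrocyte unloads
oxygen and raises the local Po2 into an *erythrocyte-associated transient*
(EAT) that relaxes between cells. Pooling decays by their timing relative
to RBC passages therefore yields three physiologically distinct numbers:
**Po2 RBC** (decays 1–3.5 ms from an RBC edge), **Po2 InterRBC** (decays at
mid-distance between RBCs, a proxy for pericapillary tissue Po2), and
**Po2 Mean** (all decays). Hemoglobin saturation follows from Po2 RBC
through the Hill equation, RBC flux from the passage count rate, and RBC
velocity from the streak angle of line-scan images.

A final, easily missed ingredient is temperature: both the zero-oxygen
lifetime and the quenching constant of the sensor drift with temperature,
and a room-temperature immersion objective cools the imaged tissue by a few
degrees. At a fixed lifetime, a colder calibration curve implies a higher
Po2 — so every conversion in this package must name its temperature, and
temperatures outside the calibrated range are a hard error rather than an
extrapolation.

## Models

**Calibration.** Per bath temperature, the Stern–Volmer relation
`1/τ = 1/τ₀ + k_q · Po2` is fitted by ordinary least squares on inverse
lifetime (`fit_calibration_curve()`). The relation is linear in the fitted
parameters, invertible in closed form, and standard for phosphorescence
quenching; the residual is reported as an RMS lifetime error. The
functional form is a package choice — the calibration could equally be an
empirical monotone spline, and the fit residual is the diagnostic for
deciding whether the linear form suffices. Between the calibrated
temperatures, `τ₀` and `k_q` are interpolated linearly
(`interpolate_curve()`); up to 0.5 °C beyond the calibrated range the
nearest curve is used (clamping, never trend extrapolation), and beyond
that conversion refuses.

**Lifetime estimation.** Accumulated decays are fitted by Poisson maximum
likelihood, `counts ~ Poisson(A·exp(−t/τ) + B)` (`fit_lifetime()`), the
natural noise model for photon counting. The fit is initialised by
log-linear regression on tail-background–subtracted counts and optimised
with box constraints; the 95% interval on τ comes from the profile
likelihood (deviance 3.84 crossings). A likelihood-ratio test against a
flat (background-only) model guards identifiability: flat input yields an
infinite interval, never a confident lifetime. The first 5.6 µs after the
gate closes (7 bins) are always discarded before fitting, removing gate
bleed-through.

**Pooling contract.** Every reported Po2 is *fit-then-convert*: the pool's
cycles are accumulated into one decay, one lifetime is fitted, and that
lifetime is converted once. Converting per-cycle lifetimes and averaging
Po2 gives a different number on EAT-modulated traces (photon counts are
lifetime-dependent, and the lifetime–Po2 map is nonlinear); the test suite
asserts the two differ so the contract stays explicit.

**EAT windows.** "1–3.5 ms around the border" is read symmetrically: a
cycle joins the border pool when its distance to the *nearest* event edge,
on the plasma side, lies in [1.0, 3.5] ms, pooling both the leading and
trailing edge. Both bounds are configurable (`eat_windows()`), since an
asymmetric edge convention is equally defensible. The inter-RBC pool uses
the centered mid-gap window of length `max(5, gap − 2·3.5)` ms, taken only
from gaps of at least 12 ms so the window can never touch a border zone —
this protects the tissue-proxy pool from EAT contamination.

**RBC detection.** The on-phase intensity is median-smoothed (3 cycles) and
compared against `baseline − f·(baseline − trough floor)` with `f = 0.5`, a
rolling-median baseline (501 cycles) and the 1% quantile as trough floor;
runs of ≥ 2 cycles below threshold become events. A signal whose dynamic
range does not exceed 4 robust noise SDs yields no events and a warning.
All constants are arguments.

**Velocimetry.** `estimate_velocity()` removes per-column means (static
structure), tiles the image into blocks, and sweeps candidate streak angles,
projecting each block's pixels onto the axis perpendicular to the candidate
direction; the count-weighted variance of the projection means peaks when
the projection runs along the streaks. The sweep is coarse (1°) then fine
(0.25°) with parabolic refinement. Velocity is
`tan(θ)·pixel_size/line_period`, signed by flow direction. Because column
mean removal would erase exactly vertical streaks, a static-dominance check
runs first: if column means carry most of the image variance, the streaks
are vertical within resolution and velocity 0 is reported with the
`low_velocity` flag — the same flag used when the best angle is within one
step of vertical.

**Saturation and comparisons.** `so2_from_po2()` implements the Hill curve
with mouse defaults (n = 2.59, P50 = 40.2 mmHg; exactly 0.5 at P50) and
`po2_from_so2()` its closed-form inverse. `compare_conditions()` pairs each
capillary across conditions and reports per-capillary deltas and percent
changes with mean ± s.e.m.; the capillary is the statistical unit, matching
how such measurements are reported, and mouse-level nesting is left as
metadata — mixed-effects inference is intentionally out of scope.

## The synthetic generator

`generate_capillary_trace()` emulates the acquisition so that every stage
has a planted truth to recover:

- RBC arrivals follow a gamma-renewal process (shape 3), more regular than
  Poisson, as expected for single-file capillary traffic; arrivals are kept
  non-overlapping with a 0.5 ms minimum plasma gap.
- True Po2 is `po2_inter + (eat_peak − po2_inter)·exp(−Δt/eat_decay)` with
  Δt the time to the nearest RBC edge, and equals `eat_peak` inside the
  RBC — a monotone exponential relaxation matching the qualitative EAT
  shape.
- Off-phase counts are Poisson around `A·exp(−t/τ(Po2, T)) + dark`, with
  the lifetime from a temperature-dependent Stern–Volmer sensor model whose
  default magnitudes (τ₀ 45→40 µs and k_q 0.90→1.00 × 10⁻³ /(µs·mmHg) over
  32.4→37 °C) are synthetic; only the *direction* of the temperature
  dependence (right shift when cooling) is treated as a physical
  constraint. On-phase counts are Poisson around a two-level
  plasma/RBC intensity.
- Line scans are dark Gaussian streaks over a bright plasma background with
  shot noise (`generate_linescan()`).

**Free parameters, chosen once.** Values the acquisition itself does not
pin down were fixed at design time: EAT relaxation constant
`eat_decay_ms = 2.0` — chosen so the 1–3.5 ms border window sits on the
elevated flank of the transient (residual `e^{−3.5/2} ≈ 17%` at its outer
edge) while mid-gap decays have essentially relaxed to the tissue baseline,
which is the premise of using Po2 InterRBC as a tissue proxy; photon rate
0.3 counts/bin at gate end (a few detected photons per decay, the
photon-counting regime); on-phase plasma/RBC levels 150/60 counts per
cycle; dark background 0.01 counts/bin/cycle. RBC transit duration is an
effective 3 µm RBC length divided by the planted velocity — 4 ms at the
resting 0.75 mm/s, lengthening when flow slows.

**Presets.** `preset()` returns ground truths for the documented
conditions: awake with a dry objective at physiological temperature
(Po2 Mean 42 mmHg, tissue baseline 31.4 mmHg, 44 RBC/s, 0.75 mm/s, 37 °C),
awake under a room-temperature immersion objective (34 mmHg, 35 RBC/s,
0.5 mm/s, 34.2 °C, tissue baseline 23.2 mmHg — the dry baseline reduced by
the reported ~26%), awake with a heated objective (identical to dry, since
heating restores the dry values), and ketamine–medetomidine anesthesia with
30% inspired O2 under a cool objective (65 mmHg at 32.4 °C; its tissue
baseline 55 mmHg, flux 30 RBC/s and velocity 0.4 mm/s are package
inventions, chosen so the capillary–tissue gradient matches the awake
conditions). The EAT peak is *not* claimed as a known value: each preset
calibrates it once by bisection (`calibrate_eat_peak()`) so that the
noise-free all-cycle fit-then-convert Po2 equals the condition's Po2 Mean
target within 0.1 mmHg, then caches it for the session.

**What the generator does not emulate.** Optical point-spread and depth
effects, detector dead time and afterpulsing, multi-exponential sensor
decays, capillary stalls, two-dye spectral bleed-through, hemodynamic
feedback between temperature and flux (condition differences are planted,
not mechanistic), and motion artifacts. Recovery tests passing on this
generator therefore validate the *analysis* — segmentation, pooling
windows, estimators, conversions, bookkeeping — not robustness to every
artifact of real recordings.

## Numerical choices and degenerate inputs

- The internal cycle holds 312 content bins of 0.8 µs (31 on + 281 off);
  250 µs at 1.25 MHz is 312.5 samples, so flat streams place cycle *i* at
  sample `floor(i·312.5)` and one second segments into exactly 4000 cycles.
  The sub-0.2% difference between 224.8 µs of stored off-phase and the
  nominal 225 µs is recorded in the gate configuration.
- Lifetime-range checks on conversion allow 2% beyond the fitted lifetime
  range (configurable); a lifetime marginally above τ₀ within that
  tolerance clamps to Po2 = 0 rather than going negative.
- Pools below 500 cycles (configurable) refuse to fit: photon-starved
  pooled decays give unstable lifetimes.
- Empty streams, empty selections, all-zero decays, constant images,
  sub-minimum images, zero baselines and out-of-range temperatures all
  raise errors naming the violated constraint; flat decays return
  non-identifiable fits rather than confident lifetimes.
- Every stochastic routine takes an explicit seed; identical seeds give
  bit-identical outputs and there is no hidden global state beyond R's RNG,
  which each generator seeds explicitly.

## Problem sizes used by the tests

The suite validates estimator accuracy at the pooled sizes the measurement
actually uses — 60,000 accumulated cycles for lifetime recovery (within 1%
of a planted 25 µs, and within 0.5% of an independent brute-force
grid-search MLE), 40,000 cycles for Po2 Mean recovery within 2 mmHg —
while end-to-end preset recovery uses 10 s acquisitions (40,000 cycles) and
12 s line scans over 5 seeds, recovering planted Po2, flux and velocity
within 10% (velocity within 5%). Calibration fits are exact to 1e-9 on
noise-free sweeps and within 5% of truth (0.5% of a grid-search oracle)
with 1% lifetime noise. These sizes were chosen to mirror the acquisition's
own pooling depth while keeping the full suite under a minute of runtime.

## Known limitations

- The Stern–Volmer form is assumed linear in inverse lifetime; strongly
  non-linear sensors would need the spline alternative and would lose the
  closed-form inverse.
- Po2 RBC pools both RBC edges; if the leading/trailing transients are
  asymmetric in real data, the pooled value averages them.
- The border pool measures the EAT flank, not its instantaneous peak: on
  synthetic data the planted edge peak exceeds the pooled Po2 RBC, and the
  generator's peak amplitude is a calibrated internal quantity, not a
  physiological claim.
- Velocity estimation assumes quasi-stationary speed within a block; use
  `windowed_velocity()` for time-resolved traces.
- The CSV acquisition container is verbose; it favors portability and
  text-only storage over compactness.
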