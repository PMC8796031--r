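---
title: "Validating beamformer and dipole-scan localization of epileptic spikes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating beamformer and dipole-scan localization of epileptic spikes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In the presurgical evaluation of focal epilepsy, interictal spikes recorded
with EEG and MEG are localized to estimate the irritative zone, and the
localization is judged against the resected (or thermocoagulated) volume of
patients who became seizure-free: a method that localizes inside or near the
resection is considered validated. The analysis chain has many knobs —
modality (EEG, MEG, combined MEEG), head-model conductivities, the inverse
method (beamformer vs. dipole scan), how the beamformer covariance is
estimated, and how strongly it is regularized. `beamspike` implements this
whole chain on synthetic data from analytic spherical head models, so every
stage can be scored against a known ground truth.

Patient recordings of this kind are not publicly available, so the package's
synthetic-data generator is a first-class module: it emulates the statistical
structure the analysis assumes (multi-trial epoched spikes, somatosensory
evoked responses, a resection volume around the true source), and all
experiments in the test suite run on it.

## Forward models

The head is a set of concentric spherical shells (`build_sphere_head`), by
default brain/skull/scalp at 0.33 / 0.01 / 0.43 S/m — the standard
three-compartment conductivities. Realistic FEM-grade six-compartment models
distinguish skull compacta from spongiosa geometrically; a sphere cannot, so
the compacta:spongiosa contrast is carried as an *effective* skull
conductivity: radial current crosses the layers in series, so
`effective_skull_conductivity()` takes the thickness-weighted harmonic mean
at a fixed compacta:spongiosa conductivity ratio (1:3.6). We make no claim
that this is equivalent to a layered skull; it is the single-parameter
analogue that the calibration procedure below can estimate.

* **EEG**: the spherical-harmonic series solution for a current dipole in a
  multilayer sphere. Per harmonic degree the shell system is solved as a
  small linear system (radii nondimensionalized for conditioning); the
  series is truncated at 60 terms by default, which changes results by less
  than 1e-8 relative against 120 terms for sources a few millimetres below
  the brain surface. In the equal-conductivity limit the series matches the
  homogeneous-sphere closed form to ~1e-13. An average reference is applied,
  so every gain column sums to zero.
* **MEG**: the closed-form field of a dipole in a spherical conductor
  (Sarvas formula) projected on radial point magnetometers. This solution is
  *exactly* independent of the conductivity profile, and a radial dipole
  produces no field — both properties are load-bearing for the calibration
  logic and are asserted bitwise/to 1e-12 in the tests. Real 275-channel
  systems use first-order synthetic gradiometers; radial magnetometers keep
  the inverse mathematics identical without modelling hardware-specific
  gradiometer synthesis.

Units are a fixed contract: mm, nA·m, µV, fT, S/m. The absolute scales are
pinned by a frozen reference fixture (six point magnetometers, one dipole)
computed with an independent sphere-model implementation.

Sources sit on a Cartesian grid clipped to the brain shell
(`build_source_grid`), 2 mm nominal spacing in the study design, without
orientation constraint. A grid point can coincide with the sphere center,
where MEG is silent; such sources are flagged and scored as zero by the
scanners rather than producing numerical noise.

## Synthetic data

`make_spike_waveform` produces a biphasic spike-and-wave template: a
monotone rising flank (20 ms), peak exactly 1.0 at t = 0, a fall into a slow
wave of opposite polarity (30% amplitude, 150 ms). Epochs are ±0.5 s at
2400 Hz by default, matching the acquisition protocol the analysis targets;
experiments in this package run at reduced rates (600 Hz) where the science
is unaffected.

`simulate_spike_trials` projects the waveform through the leadfield and adds
noise. Choices that matter:

* **SNR definition**: the study protocol never quantifies spike SNR, so we
  define it as single-trial signal amplitude at the spike peak on the best
  channel divided by the per-channel noise standard deviation. Averaging n
  trials then improves the evoked SNR by ~√n, which is asserted by a
  Monte-Carlo test.
* **Noise**: temporally AR(1) (coefficient 0.95) carrying 80% of the
  variance plus white sensor noise. A purely white option is retained for
  analytic checks. The AR component gives the covariance matrix non-trivial
  structure, without which beamformer regularization would be uninteresting.
* **Trial-to-trial variability**: lognormal amplitude jitter (sdlog 0.2) and
  uniform latency jitter (±5 ms), both on by default. These are what make
  the average-based and event-related covariances genuinely different
  estimators; with one trial the two are identical (asserted exactly).
* Spike-count presets follow the two study scenarios: 248 and 54 averaged
  spikes.

What the generator does **not** emulate: artifacts (blinks, cardiac), spike
propagation along the cortex, realistic cortical geometry or sensor noise
spectra. Passing tests therefore demonstrate correctness of the machinery
and recoverability under the stated statistical conditions — not clinical
performance on real data.

## Preprocessing

Filtering is two-pass (zero-phase) Butterworth, 2–80 Hz with a 50 Hz notch,
order 6. Numerically the high-pass is implemented as a cascade of
second-order sections: a single order-6 polynomial at a 2 Hz corner under a
2400 Hz rate is unstable in double precision. Data are demeaned first (the
high-pass removes DC anyway) and odd-reflection padding suppresses
forward–backward edge transients.

The localization time point is the middle of the rising flank of the
averaged spike. The study describes this verbally; our operational rule, on
the global-field-power (RMS across channels) time course: the onset is the
last pre-peak sample at or below 20% of the peak amplitude, and the midpoint
is the first sample after onset reaching 50% of the peak amplitude. For a
linear ramp this is exactly halfway up the flank; both thresholds are
configurable.

For combined MEEG, each channel (data *and* leadfield row) is divided by its
baseline noise standard deviation, estimated from the averaged data in the
−500 to −300 ms window, making both modalities unit-free before stacking.
One caution: channelwise weighting does change the dipole-scan projector in
general (a weighted least-squares fit is not the unweighted one), so gof
maps are only invariant under a *uniform* rescale; what survives channelwise
weighting exactly is the noiseless on-grid identity gof = 1 at the true
source. The test suite asserts precisely these two facts.

## Inverse solvers

The beamformer at source p with unit orientation φ minimizes the output
power `W'CW` subject to `W'Lφ > 0` and `‖W‖ = 1`. The optimal orientation
is the eigenvector of the smallest generalized eigenvalue of
`(L'C⁻²L, L'C⁻¹L)`; the filter is `W = C⁻¹Lφ / ‖C⁻¹Lφ‖`. Note that the
frequently printed closed form `W = C⁻¹Lφ / (Lφ'C⁻²Lφ)` normalizes by the
*square* of `‖C⁻¹Lφ‖` and therefore violates the `‖W‖ = 1` constraint it is
derived under; the two are parallel and differ by that scalar. We default to
the constraint-honoring unit-noise-gain form (`variant = "unit_norm"`) and
retain the literal form as `variant = "as_printed"` for comparison — their
power maps are not interchangeable and are reported separately.

Numerical choices: covariance inverses go through a symmetric
eigendecomposition with a relative eigenvalue floor of 1e-12; a
rank-deficient covariance at α = 0 is an explicit error instructing
regularization, not a silent pseudo-inverse (this surfaces, rather than
hides, the well-known α = 0 pathology of average-based beamformers on short
windows). Near-null gain directions — the magnetically silent quasi-radial
MEG orientation — are projected out of the orientation eigenproblem. When
all generalized eigenvalues coincide (C ∝ I), every orientation is optimal
and the dominant right-singular vector of L is returned as a deterministic
fallback. Argmax ties break to the lowest source index, a real possibility
since near-equal power on neighbouring grid points is exactly the mechanism
behind jumpy distance curves.

Two covariance estimators feed the beamformer: `average_based` (second
moment of the averaged spike) and `event_related` (pooled second moment of
the single trials). Both default to the full ±0.5 s epoch — the source
document does not state its window — and both filters are applied to the
*averaged* data for localization. Localization uses the single
analysis sample by default; a multi-sample window is supported.

The dipole scan fits `m = L⁺D` at every grid point and reports
`gof = 1 − ‖D − LL⁺D‖²/‖D‖²`. No regularization for EEG and MEEG; for
MEG-only scans each S×3 gain is reduced to its two strongest singular
directions (tSVD), discarding the quasi-radial one. In a sphere the radial
column is numerically null, so the 2- and 3-column scans agree to 1e-6 —
asserted as an equivalence oracle.

## Skull-conductivity calibration

Skull conductivity varies strongly between individuals and is the parameter
EEG forward models are most sensitive to, while spherical MEG is exactly
insensitive to it. The somatosensory P20 component (median-nerve
stimulation; focal, tangential) provides the anchor: (1) a tSVD MEG dipole
scan at the P20 sample fixes the location, (2) the EEG fits the orientation
with the candidate-conductivity gain (full 3-moment least squares — at the
optimum this equals orientation-only fitting and has a simpler contract),
(3) the MEG fixes the amplitude, (4) the EEG residual variance is stored.
The candidate with minimal residual variance is the calibrated conductivity.

The default search grid is 10 log-spaced values in [0.0021, 0.033] S/m,
bracketing the published range of skull-conductivity estimates and
containing the standard 0.01 S/m; the grid is fully configurable, and
recovery is judged "within one grid step". Under the package's recovery
conditions (SNR 10, 600 trials, 20 seeds) the generating value 0.0125 S/m is
recovered within one step in every seed, and exactly (residual variance 0)
in the noiseless limit.

## Evaluation

`make_resection` defines the reference volume as all grid points within a
ball of the true source (6.9 mm radius ≈ the 1.4 cm³ thermocoagulation
scale; 12.4 mm ≈ the 8 cm³ resection scale). Two metrics per map:

* **resection distance** — 0 if the argmax is a member, else the distance to
  the nearest member point (grid-limited to ~one spacing; we report 0.1 mm
  resolution);
* **relative power** — max map value outside the resection over max inside;
  below 1 implies the global maximum is inside, hence distance 0 (asserted
  on every sweep record).

`regularization_sweep` runs every method × modality × model over α from 0 to
0.2 in steps of 0.002 (101 values; toolbox default 0.05 included). Dipole
scans do not depend on α and are computed once. Failures in individual cells
(e.g. singular covariance at α = 0) are recorded with a note rather than
aborting the sweep, mirroring how α = 0 pathologies are reported rather than
hidden. `run_pipeline` wires everything together and emits the sweep table,
a best-α summary and a JSON manifest (config + seed + versions) that replays
to identical output.

## Problem sizes and reproducibility

The analyses in the tests and in `scripts/acceptance.R` run at reduced
sizes chosen as the package's desk-scale study conditions: 40 EEG + 60 MEG
sensors, 600 Hz sampling, a 14 mm source grid (~700 sources), 10–26 α
values, 20 calibration seeds and 5 localization seeds at SNR 5. The
defaults of the generator itself keep the full protocol scale (2400 Hz,
±0.5 s, 70/271 channels, 2 mm grid, 248/54-spike presets); a full-scale run
is the same code with larger inputs. All randomness flows through a single
integer seed per dataset; identical (config, seed) pairs are bit-identical.

## Known limitations

* Spherical geometry only: no realistic MRI-derived compartments, no
  white-matter anisotropy, no separate skull compacta/spongiosa layers.
* Radial magnetometers instead of synthetic gradiometers.
* The resection is a geometric ball around the truth — real resections are
  irregular and not centred on the generator.
* Reported headline numbers from patient studies (specific distances, gof
  percentages, calibrated conductivities) depend on private clinical
  recordings and are not reproduced here; the package validates the
  machinery and its recoverability properties instead.
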