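---
title: "Pace-mapping localization: models, protocol emulation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pace-mapping localization: models, protocol emulation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacemapr)
```

## The problem

Premature ventricular contractions originate at a focal site whose position
largely determines the QRS morphology seen on the 12-lead surface ECG. Pace
mapping exploits this: candidate endocardial sites are stimulated and the
paced morphology compared to the clinical arrhythmia until a match is
found. `pacemapr` implements four automated localizers that, given a set of
*modeling sites* (position and ECG known), predict the position of a
*target site* from its ECG alone, together with an emulation of the
round-by-round clinical workflow and the associated outcome metrics.

All positions are patient-local Cartesian coordinates in millimetres;
voltages are millivolts. No anatomical registration is attempted.

## Signal representation

Each site's beats are averaged elementwise into a representative beat
(`average_beats`); beats are assumed pre-aligned within a site, so no
cross-correlation realignment is applied before averaging. Morphology
comparisons operate on the *splice vector*: the twelve per-lead windows of
150 ms cut around a common alignment point and concatenated in the
canonical lead order (I, II, III, aVR, aVL, aVF, V1–V6).

The alignment point is the maximum of the *composite signal*. Several
reasonable definitions exist (per-sample RMS, vector magnitude of a lead
subset); the package uses the per-sample sum of absolute voltages across
the twelve leads, which gives a single robust alignment point without sign
cancellation between leads. Argmax ties are broken toward the earliest
sample, and with an even window length W the window starts ⌊W/2⌋ samples
before the center. Windows that would cross a recording edge raise an
error rather than being padded or truncated, since asymmetric windows
would silently distort every downstream metric.

QRS onset, needed for the QRS-integral predictors, is detected
automatically (manual annotation is not reproducible): searching backward
from the composite maximum, the onset is the earliest sample of the
contiguous run on which the composite stays above 5% of its maximum. The
threshold trades early-noise immunity against detection delay; on
gradually building signals the crossing can land one or two dozen
milliseconds after the true activation start, which is characteristic of
threshold detectors and harmless to the regression (all sites are treated
consistently).

## The four localizers

**QIM.** Each coordinate is regressed on an intercept plus the signed
initial 120-ms QRS integrals of leads III, V2 and V6 (trapezoidal, mV·ms).
Signed integrals are essential: rectified areas would discard the
directional information the regression relies on. At least five sites are
required for the four-parameter system; rank-deficient designs (e.g.
nearly collinear pacing sets) are solved by the SVD pseudo-inverse and
flagged in the fit diagnostics.

**DEM and DCM.** A scalar morphology metric is calibrated against
inter-site Euclidean distance by an origin-constrained least-squares slope
`k = Σ(d·m)/Σ(m²)`, using all pairs of modeling sites. For DEM the metric
is `E12`, the sum over leads of the per-lead RMS voltage difference (the
1/N normalization sits inside the per-lead square root, with N the window
length in samples); for DCM it is `1 − Corr` with `Corr` the mean per-lead
Pearson correlation, so that estimated distances are nonnegative. A lead
that is constant in either input has no defined correlation and is
excluded from the average rather than propagating NaN; fully degenerate
pairs raise an error. Estimated target distances (clamped at zero) feed a
multilateration step minimizing `J = Σᵢ(‖x − aᵢ‖ − d̂ᵢ)².`

**DDM.** The transfer-matrix model assumes that locally, waveform
differences between sites and position differences between sites are
related by one linear map, so any waveform difference expressible in a
basis of known-pair waveform differences can be carried into the spatial
domain with the same coefficients. For m modeling sites the basis uses all
C(m, 2) ordered pairs i < j; the pair basis is symmetric in the sites,
avoids privileging a reference site, and for affine data is deliberately
redundant (the differences span at most m − 1 dimensions), which the
minimum-norm least-squares solution handles: coefficient ambiguity lies in
the null space of the position differences too, so the spatial
reconstruction is unique. The prediction averages `Pᵢ + ΔP*ᵢ` uniformly
over modeling sites; uniform weighting is the natural generalization of
the three-site mean to larger modeling sets.

With exact position-affine waveforms, DDM recovers any target in the
affine span of the modeling sites to machine precision, and projects
out-of-span targets orthogonally onto that span — both properties are
asserted in the test suite.

## Numerical choices

* All least-squares systems go through one SVD-based solver: singular
  values below 1e-8 of the largest are dropped (minimum-norm solution,
  rank flag set); if the SVD itself fails, a small relative ridge
  (1e-8·max²) is added instead.
* Multilateration is nonconvex (coplanar anchors have mirror minima), so
  the solver polishes several starts and keeps the lowest cost: the
  inverse-distance-weighted anchor centroid, every anchor, and — with four
  or more anchors — the linearized trilateration solution obtained by
  subtracting squared-distance equations, which is exact for consistent
  distances and protects against local-minimum traps. Each start is
  refined by Nelder–Mead then a BFGS polish with the analytic gradient.
* "Farthest"/"nearest" ties anywhere in the protocol break by
  lexicographic site id, keeping every run deterministic.
* Distance comparatives follow their wording: the hit radius (15 mm) and
  the range-scheme neighborhood (35 mm) are inclusive; the hit-rate
  neighbor band (15, 35) and the credibility cutoff (beyond 35 mm) are
  exclusive.

## Protocol emulation

`run_protocol` initializes with the potential modeling sites farthest from
the target (five for QIM, three otherwise), then iterates: predict;
terminate on a hit (≤ 15 mm) or when no unused sites remain; otherwise add
one site — the unused site nearest a credible prediction when it lies
within 15 mm of it, else the site farthest from the geometric center of
the current modeling set. The hit test is evaluated before the exhaustion
test so that a successful final round counts as a hit. A `fixed` variant
replaces the adaptive choice with the unused site farthest from the
target, making the site sequence a pure function of geometry (useful for
sensitivity analyses, and verified model-independent in the tests).

The emulation is retrospective: hit and credibility checks use the
target's true pacing coordinate, exactly as when replaying recorded
pacing data with known ground truth. Traces record this explicitly; no
claim of prospective clinical guidance is implied.

Outcome classification distinguishes an *early termination* — the trace
ran out of potential sites while its estimated error was still strictly
improving on the previous round — from a plain miss. This operationalizes
a one-sentence clinical definition and is flagged as an interpretation;
single-round exhausted traces count as misses. Estimated-error curves hold
each trace at its running minimum ("the error remains unchanged after
minimization"); reduced distances (minimum modeling-site distance minus
estimated error) exclude rounds after the trace's minimum error has been
reached. Target-range tables report Mean/Std/Mid (median) of the initial
radius, final estimated error and modeling sites used, with two-sided
*paired* t-tests between models — pairing is the defensible choice since
all models run on identical targets; identical inputs are guarded to
p = 1 rather than NaN.

## The synthetic generator

`make_dataset` emulates a pace-mapping patient: by default 25 sites (the
mean per-patient site count in published multi-site pacing datasets) on an
ellipsoidal shell with semi-axes 25 × 25 × 45 mm (ventricle scale), at
least 12 mm apart, each with 28 beats and 0.05 mV per-sample Gaussian
noise. Two forward models map position to waveform:

* **isotropic-conduction** — activation spreads from the pacing site at
  0.7 m/s (chord distance approximates the geodesic); each of 500 shell
  patches contributes a dipole oriented away from the source with a 4-ms
  Gaussian activation pulse, projected onto twelve fixed unit lead axes
  (frontal-plane limb leads at their standard angles; precordial axes
  sweeping from right-anterior to left-lateral). Amplitudes are scaled to
  QRS-like millivolt range.
* **affine** — waveforms are exactly affine in position: a shared
  QRS-like template (sharp onset, distinct composite spike) plus
  position-coupled discrete sine harmonics on a sub-window, mutually
  orthogonal with equal norms per lead. This makes E12 *exactly*
  proportional to inter-site distance, the QRS-integral predictors exactly
  affine, and the composite argmax and detected onset invariant across
  sites — so QIM, DEM and DDM have closed-form ground truth against which
  machine-precision recovery is asserted.

What the generator does *not* emulate: torso volume conduction,
anisotropic fiber conduction, baseline wander, powerline artifacts, beat
misalignment, and anatomically realistic geometry. Passing tests therefore
demonstrate algorithmic correctness and calibrated behavior under the
stated model, not clinical performance.

## Known limitations

The DCM calibration is structurally biased on smooth forward models:
Pearson correlation is a smooth function of the waveforms, so `1 − Corr`
grows quadratically, not linearly, with small position offsets; a
through-origin linear calibration then systematically distorts estimated
distances, and DCM's recovery error on exact affine data remains at the
millimetre-to-centimetre scale where DEM is exact. The test suite
documents a second consequence: additive beat noise inflates every
`1 − Corr` value by a near-constant offset, which can *partially correct*
the quadratic bias, so DCM's median error is not monotone in the noise
level. Both effects are consistent with DCM ranking last among the four
models in comparative evaluations.

QIM depends on a stable automated onset; on the conduction-model beats the
5% threshold detects onset 15–20 ms after the pacing instant because the
early wavefront's net dipole nearly cancels. The shift is consistent
across sites and leaves the regression well-posed.

## Problem sizes used by the test suite

Validation runs are sized for interactive use: oracle comparisons use 100
random instances per operation; exact-recovery checks use one 25-site
affine patient; the noise study uses one 25-site affine patient with four
beats per site and 50 noise replicates per level (0, 0.01, 0.05, 0.2 mV);
end-to-end CLI checks use 20-site conduction-model patients with two beats
per site. The full-scale defaults (28 beats, 0.05 mV) are exercised by
`scripts/acceptance.R`.
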