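---
title: "Micro-movement spikes and causal gait networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-movement spikes and causal gait networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmms)
```

This vignette is the package's account of its own methods: the models and
their assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, the numerical choices, and the places where the
design was genuinely open.

## 1. Micro-movement spikes

A kinematic series (angular speed in rad/s, acceleration in m/s², the
Euclidean norm of a 3-D position) is reduced to its sequence of local peaks.
Each peak amplitude `p` is standardized by the mean `m` of the two local
minima flanking it:

$$v = \frac{p}{p + \tfrac{1}{2}(m_\text{before} + m_\text{after})} \in (0, 1].$$

Because `p` exceeds both flanking minima, `v` in fact lies in (1/2, 1] for
signals with positive troughs, reaching 1 only when both minima are zero.
The ratio cancels any common amplitude factor — sensor gain, limb length,
body size — which is the point of the standardization: subjects become
comparable in one unitless scale. The spike *times* carry the complementary
information; their successive differences are the inter-peak intervals used
throughout the timing analyses.

Design choices:

- **Plateaus** (runs of equal samples) count once, at their first sample —
  a deterministic tie-break.
- **Boundary peaks** keep the series' boundary sample as their missing
  flanking minimum rather than being discarded.
- **No prominence filter by default.** Whether a minimum-prominence filter
  should precede standardization is an open choice; none is applied unless
  requested (`detect_peaks(min_prominence = )`). The band-stop probe is the
  one place a relative prominence floor is applied internally, to keep
  numerical filter ripple out of a before/after comparison (Section 5).
- **Exact scale invariance.** The ratio is scale-invariant in exact
  arithmetic but not bitwise in floating point: `fl(c*p)` and `fl(c*m)`
  round independently, and roughly a third of values change in their last
  bit under `c = 10`. Normalized amplitudes are therefore snapped to a
  `2^-26` grid (≈1.5e-8, far below any sensor's amplitude resolution), which
  makes `mms(c * x)` literally identical to `mms(x)` while perturbing no
  scientific quantity at any tolerance used in the package.
- **Gamma centering.** The amplitude distribution is fitted by a
  maximum-likelihood gamma and the fitted mean (shape × scale) subtracted.
  The MLE is computed by a Newton solve of the profile-likelihood equation
  `log(a) − digamma(a) = log(mean) − mean(log v)` rather than by a generic
  optimizer: the profile solve is deterministic and scale-equivariant to
  machine precision, properties the package's invariance tests rely on.
  Series with fewer than 20 spikes (configurable) report their signature as
  missing rather than fitting.

## 2. The single-internal-delay causality model

For two centered spike-amplitude series `x` (effect) and `y` (candidate
cause), the package compares

$$x_n = a_1 x_{n-l} + w_{1,n}, \qquad
  x_n = a_2 x_{n-l} + b\, y_{n-l} + w_{2,n}$$

at each candidate internal delay `l`, and scores the causality as
`GC(l) = log(σ₁²/σ₂²)`. `GC > 0` means the past of `y` improves the
prediction of `x`. The delay grid default is 1..50 spike lags, capped at a
quarter of the series length; the grid maximizer is the **optimal lag** (an
internal motor timing, in units of inter-peak steps), and
`force = max GC / optimal lag` summarises both the strength and the speed of
the directed influence.

Two estimator modes are provided, because the closed-form moment equations
and the least-squares normal equations are not the same estimator:

- **`mode = "paper"`** solves the printed closed-form system verbatim:
  `a1 = Rxx(0)/Rxx(l)`, the 2×2 system
  `Rxx(0) = a2 Rxx(l) + b Rxy(l)`, `Rxx(l) = a2 Rxx(0) + b Rxy(0)`, and
  `σ₁² = (1 − a1²) Rxx(0)`,
  `σ₂² = (1 − a2²) Rxx(0) − b² Ryy(0) − 2 a2 b Rxy(0)`.
  These equations drop noise–regressor cross-moments that are nonzero under
  the generative model, so on real data the implied "variances" can be
  negative (the hand-derivable example `Rxx0=2, Rxxl=1, Ryy0=1, Rxy0=0.25,
  Rxyl=0.5` yields σ₁² = −6, σ₂² = −14). The **strict** validity policy
  marks such lags invalid; the **permissive** policy accepts any lag whose
  variance *ratio* is positive (the example then scores `log(3/7)`).
  Strict is the default: it makes the estimator's failure mode explicit
  instead of silently exponentiating a complex logarithm.
- **`mode = "ols"`** solves the standard least-squares normal equations with
  residual variances `σ² = Rxx(0) − (explained covariance)`. This mode is
  consistent for the generative model (it recovers `a2 = 0.5, b = 0.4` to
  within 0.02 at n = 10⁵), keeps GC non-negative up to sampling noise, and
  is the mode used by the recovery and calibration analyses.

Whether the reciprocal form of `a1` in the closed-form system was intended
or an artifact cannot be decided from the equations themselves; shipping
both modes, with `paper` as the replication default and `ols` as the
statistically consistent alternative, records the discrepancy instead of
guessing.

**Lag units.** Spike-indexed series (one value per detected peak) are the
default domain, so one lag is one inter-peak step whose physical duration
varies with the subject's cadence. Sample-indexed series can be passed
directly when a fixed 1/Fs lag unit is wanted; the estimator is agnostic.

**Significance.** The null is built by circularly shifting the candidate
cause and recomputing the maximal GC per surrogate;
`p = (1 + #{surrogate ≥ observed}) / (1 + B)`, with `B = 199` by default
(999 for final runs) and α = 0.01. Offsets are drawn at least 4× the
maximum lag away from alignment (capped by a third of the series): for
strongly autocorrelated gait series, shifts just beyond the lag grid still
carry correlation and would leak signal into the null, destroying power.
Under independence the test holds its size (measured type-I error within
Monte-Carlo bands at both 1% and 5%). A **feedback loop** is declared when
both directions of a pair are individually significant with positive
maximal GC — causality in both directions.

**Networks.** Per node, the out-degree counts significant outgoing edges;
the asymmetry index is the normalized L1 directional difference
`Σ|GC(i→j) − GC(j→i)| / Σ(GC(i→j) + GC(j→i))` over pairs whose two
directions both carry valid positive GC (0 for symmetric flow, toward 1 for
one-way flow). The index formula is a package choice — any monotone
alternative would order subjects similarly — and is documented rather than
hidden. Group feedback maps report, per unordered node pair, the percentage
of subjects in whom a feedback loop was detected.

## 3. Frequency-domain coupling

Cross-coherence is the segment-averaged (Welch) magnitude-squared
coherence: 4-s Hann-tapered segments, 50% overlap — at least eight segments
on a 3-minute walk while resolving the gait band near 1 Hz. The **coupling
frequency** is the non-DC coherence maximizer (DC is trivially coherent for
nonzero-mean spike trains; ties resolve to the lowest frequency). The
spike-train representation places each normalized amplitude at its peak
sample with zeros elsewhere (linear interpolation is available), so the
analysis sees the full time series, not only the peak sequence; raw
kinematic series can be passed just as well, and both conventions are
supported because the choice is genuinely ambiguous. The mean frequency of
a spectrum is the plain power-weighted average `Σ f P / Σ P`.

## 4. Stochastic signatures

- **Gamma NSR.** The MLE gamma scale of the uncentered amplitudes is the
  noise-to-signal ratio (for a gamma variate, variance/mean = scale).
- **Dip statistic.** The Hartigan dip — the sup-distance from the empirical
  cdf to the nearest unimodal cdf — is computed exactly from the
  gate/greatest-convex-minorant characterisation with bisection over the
  distance (tolerance 1e-10): a candidate distance is feasible when, for
  some mode placement, a convex chain threads the gates left of the mode, a
  concave chain threads them on the right, and the two chains can join. An
  independent linear-programming oracle over the same function class
  verifies the construction exactly at small n in the test-suite; p-values
  come from a seeded uniform bootstrap (B = 2000 by default) rather than
  asymptotic tables.
- **Mode decomposition.** A two-component mixture — an exponential anchored
  at the sample minimum for the low, memoryless amplitudes and a Gaussian
  for the rhythmic mode — is fitted by EM with a deterministic
  lower-quartile initialisation. Points are assigned by maximal posterior
  responsibility; `mode1_fraction` is the assigned count share (the
  "highest activity" reading of dominance; amplitude-sum share would be the
  alternative). Mixture weights pinned within 2% of 0 or 1 are flagged
  "effectively unimodal" rather than interpreted. EM log-likelihood
  monotonicity is asserted in the tests.
- **Amplitude–timing dependence.** A 2-D histogram of (amplitude, preceding
  interval) with a chi-square diagnostic on a coarse quantile partition
  quantifies departure from the common independence assumption; it is a
  diagnostic, not a test of the method.

## 5. Stratification and the stride proxy

The stride proxy divides mean COM speed (m/s) by the mean frequency of the
demeaned speed spectrum (1/s): meters per stride. Spectra are demeaned so
the DC bin cannot drag the mean frequency toward zero. Feature tables are
min-max normalized by default (z-scores available); constant features are
flagged and zeroed, never divided by zero. Clustering is plain Euclidean
k-means with seeded restarts and a silhouette report; k is always the
user's choice (a silhouette scan helper suggests but never overrides).
Group timing-difference maps use Welch two-sample t-tests per node at
α = 0.05 with no multiple-testing correction by default, zeroing
non-significant entries (mirroring per-node significance maps at a fixed
alpha); Benjamini–Hochberg is available.

The band-stop probe quantifies how much of the gamma NSR a candidate tremor
band carries: zero-phase Butterworth band-stop filtering, then MMS + NSR
recomputed. Two numerical guards make the comparison honest: a 2-s margin
at both ends removes the forward–backward filter's start-up transients, and
a prominence floor at 5% of the unfiltered median peak prominence keeps
sub-resolution filter ripple from registering as spikes. Whether a tremor
band raises or lowers the measured NSR depends on the tremor amplitude:
low-amplitude high-frequency ripple concentrates amplitudes near 1/2 and can
*lower* the gamma scale, while strong tremor inflates it. The probe reports
both numbers and leaves the interpretation to the analyst.

## 6. The synthetic generator: what it emulates, what it does not

`simulate_subject()` builds, per node, a rectified quasi-periodic carrier:
one raised-sine bump per stride cycle with troughs at a fixed floor, cycle
periods jittered by a log-normal multiplier (5% sd by default) around a
cadence near 1 Hz, and per-cycle peak amplitudes drawn so that the planted
*normalized* amplitudes are gamma distributed (shape 100, scale 0.007 —
mean 0.7, spread 0.07, comfortably inside the representable (1/2, 1)
interval) or drawn from an exponential + Gaussian mixture when a two-mode
regime is wanted. Directed couplings act at the spike level: the source's
centered amplitude sequence, delayed by the planted lag, is added into the
target's amplitudes with the planted gain — exactly the structure the
causality model assumes, in the spike-indexed units the model reads.
Optional tremor sinusoids and additive Gaussian noise contaminate the
carrier. A `com_speed` channel with configurable mean speed (1.2 m/s) and a
single oscillation per stride supports the stride-proxy analyses. All draws
derive from one seed; identical seeds give bit-identical recordings.

What it does *not* emulate: biomechanical coupling between joints, postural
drift, turning, pauses, sensor dropout, or measurement noise structure
beyond additive Gaussian + sinusoids. Passing tests therefore demonstrate
that the *pipeline* recovers planted structure of the kind the models
assume; they do not certify performance on real pathological gait, where
model misspecification (non-stationarity, amplitude–timing dependence) is
the norm rather than the exception.

Problem sizes used by the validation suite and the acceptance script are
chosen to make the Monte-Carlo bands meaningful at desk scale: 100 seeds at
5·10⁴ samples for lag recovery, 500 replicates for test-size checks, 200
planted pairs for feedback operating characteristics, 20 seeded cohorts
(2 groups × 3 subjects × 2-minute walks) for end-to-end separation.

## 7. Known limitations

- The single-delay model is deliberately minimal; distributed lags,
  conditional (multivariate) causality and spectral causality decompositions
  are out of scope.
- Pairwise causality on a shared-driver network can report genuine
  (pairwise) but indirect edges; the star-topology tests use a white driver
  precisely to isolate direct edges.
- The closed-form `paper` estimator can invalidate lags on real data (by
  design, under the strict policy); analyses that need a defined value for
  every lag should use `ols`.
- The dip test's bootstrap null is the uniform; for heavily tied data the
  dip itself remains exact, but the uniform null is conservative.
- Circular-shift surrogates assume approximate stationarity over the walk.
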