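---
title: "Wave decomposition, propulsion and escape-response analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave decomposition, propulsion and escape-response analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finwave)
```

# The scientific problem

Adult zebrafish carrying hypomorphic *zfyve26* (Spastizin/SPG15) alleles show
a distinctive locomotor phenotype: they hold station in a current less well
than wildtype siblings, swim with a slightly reduced thrust velocity, bend
their bodies more strongly, and show a pectoral bending peak shifted towards
the tail. The working interpretation is that degeneration of the longest
motor neurons stiffens the caudal body first, damping the thrust-generating
travelling wave, and that the fish partly compensate with an enlarged
pectoral standing wave. `finwave` packages the quantitative machinery needed
to state and test that interpretation on data: a parametric wave model with
a propulsion layer, a video midline tracker, kinematic and arena-occupancy
features, Mauthner-cell field-potential analysis, axon morphometry with
operator blinding, and the statistics layer used throughout. Because no raw
recordings are distributed, every input has a synthetic generator with
ground truth, and the whole pipeline is validated against those generators.

# The kinematic wave model

Body undulation is described by the local bending angle per segment,
$\theta(s, t)$, on arc-length fractions $s \in [0,1]$ (0 = snout,
1 = tail tip; angles in radians, positive counter-clockwise):

$$
\theta(s,t) \;=\; A_s\, G(s)\, \cos(2\pi f t)\;+\;
\gamma(s)\, A_t\, s^{q}\, \cos\!\left(2\pi f t - \frac{2\pi s}{\lambda}\right)
$$

* the first term is the **pectoral standing wave**: a Gaussian envelope
  $G(s) = \exp\{-(s - s_0)^2 / 2w^2\}$ with unit maximum at the peak
  position $s_0$, oscillating in place;
* the second is the **caudal travelling wave**, with base amplitude $A_t$,
  power-law caudal growth $s^q$, and wavelength $\lambda$ in body lengths;
* $\gamma(s)$ models caudal stiffening: 1 rostral to the onset
  (default mid-body, $s = 0.5$), dropping to `stiffness_gamma`
  caudally across a half-cosine ramp of width 0.05 BL, so curvature stays
  continuous and the reconstructed midlines are smooth.

No equations for this model are fixed by prior work; this parametrization is
the package's normative definition (recorded in the configuration schema so
alternatives can be swapped in). It is the minimal form that realizes the
three conditions of interest: **fully flexible** ($\gamma = 1$), **stiff**
($\gamma < 1$), and **compensated** (stiff plus an enlarged, caudally
shifted standing wave).

Midlines follow from bending by integrating unit tangents with segment
length $L/n$, which makes the body inextensible by construction; the inverse
(`bending_series()`) recovers $\theta$ exactly, and the package tests that
round trip to $10^{-6}$ rad.

## Shipped presets and their calibration

| preset | $\gamma$ | $A_s$ (rad) | $s_0$ | notes |
|---|---|---|---|---|
| flexible (wildtype) | 1.0 | 0.040 | 0.25 | $A_t = 0.05$, $q = 2$, $\lambda = 1$ BL, $f = 2.5$ Hz |
| stiff | 0.3 | 0.040 | 0.25 | stiffening caudal to $s = 0.5$ |
| compensated | 0.3 | 0.072 ($\times 1.8$) | 0.35 | peak shifted caudally |

The numeric values are repository choices, fixed once: amplitudes give a
tail-beat excursion of a few millimetres on a 30 mm fish (realistic for slow
cruising), $f = 2.5$ Hz and $\lambda \approx 1$ BL are typical of adult
zebrafish cruising, and the stiff/compensated offsets were chosen so the
three presets produce the qualitative condition ordering (stiff slowest,
compensated back near flexible). They are deliberately round numbers, not
fits to data.

# Wave decomposition

`fit_single_frequency()` estimates the dominant tail-beat frequency from the
mean power spectrum of mean-subtracted bending over mid-body segments, then
least-squares fits a single tone per segment, giving a complex amplitude
profile $Z(s)$. `decompose_standing_travelling()` splits $Z$ into
counter-propagating components by the spatial analytic signal (the discrete
Hilbert transform along $s$): $Z = Z_+ + Z_-$, standing amplitude
$2\min(|Z_+|, |Z_-|)$, travelling amplitude $||Z_+| - |Z_-||$, and a
per-segment travelling index in $[0,1]$ (0/0 defined as 0). For a purely
standing field the two halves are mirror images and the index is 0; for a
pure travelling wave one half carries everything and the index is 1. The
index decreases monotonically with caudal stiffening, which the test suite
checks on a $\gamma$ grid.

The **pectoral bending peak position** is the argmax of the amplitude
envelope $|Z(s)|$ restricted to the front half of the body, refined by
parabolic interpolation, with ties broken rostrally. How this quantity was
computed from tracked data in prior work is not recorded; the envelope
argmax over a rostral window is this package's operational definition, and
both the window and the refinement are parameters.

# Propulsion and the recoil correction

Mean thrust uses Lighthill's elongated-body form, which depends only on
tail-tip kinematics:

$$
T(U) = \frac{m_a}{2}\left(\langle \dot h^2 \rangle -
U^2 \langle h'^2 \rangle\right), \qquad
m_a = \rho\, \pi\, (\text{span}/2)^2 ,
$$

balanced against quadratic body drag
$D(U) = \tfrac12 \rho C_d A U^2$; the steady speed is the bisection root of
$T(U) = D(U)$ (residual below $10^{-8}$ of the drag scale) and is reported
in body lengths per second, the unit used for all condition comparisons. A
resistive-force model would be a legitimate alternative backend; the
elongated-body form was chosen because it is the simplest closed form with
tail-only dependence.

A subtlety decides the biology. If tail kinematics are measured in a
head-pinned frame, a bend placed rostrally always swings the tail more
(longer lever arm), so a compensating standing wave would always prefer the
most rostral position — the opposite of the observed caudal shift of the
pectoral bending peak in mutants. But a swimming fish is laterally force-
and torque-free: prescribed bending is accompanied by a rigid **recoil**
that keeps net lateral momentum and angular momentum at zero.
`recoil_frame()` applies the position-level (small-recoil) form of this
constraint — each midline is translated to its mass centroid and rotated to
its mass-weighted principal axis, with uniform mass per unit length. For a
localized bend of angle $\theta$ at position $s_0$ on a uniform body, the
recoil-corrected tail displacement works out to
$\theta L\, s_0^2 (1 - s_0)$ — maximal at $s_0 = 2/3$, so *caudal*
placements genuinely move the tail more once recoil is accounted for. This
single, standard piece of swimming mechanics is what lets the model
reproduce the caudal compensation: `compensation_search()` grid-searches
standing amplitude and peak position at fixed caudal stiffness and selects
the least-effort combination (smallest amplitude within 5% of the flexible
speed, most caudal on ties), which lands caudal to the wildtype peak.
`tail_kinematics(..., recoil = FALSE)` is available for oracle tests against
externally prescribed tail motion.

Uniform mass per unit length is a simplification (a real fish is
head-heavy); it keeps the recoil correction parameter-free and the analytic
$s_0^2(1-s_0)$ story exact. A width-squared mass profile shifts the optimum
but preserves the caudal preference.

# Synthetic data: what it emulates, what it does not

* **Videos** (`render_frames()`): a filled silhouette (midline swept by a
  tapering width profile) on a brighter background with Gaussian pixel
  noise, 8-bit, deterministic per seed. Cruising defaults are 200 fps / 30 s
  and escape defaults 936 fps / 5 s, matching the recording conditions the
  pipeline targets; tests use shorter clips of the same construction. The
  renderer does **not** model fins, shadows, refraction, occlusions or
  non-uniform lighting, so tracker performance here bounds real-data
  performance from above.
* **Arena trajectories** (`simulate_arena_track()`): a reflected random walk
  whose wildtype preset has an Ornstein-Uhlenbeck pull (1.5 s$^{-1}$) to the
  longitudinal centre line and whose mutant preset has no pull and larger
  step dispersion — the minimal mechanism that reproduces
  "wildtype holds the centre, mutants disperse". Stream speed labels
  (slow/medium/fast for the three pump flows of 172, 240 and 277 ml/s) are
  categorical metadata: the mapping from flow to local water speed is not
  derivable, so no hydrodynamic coupling is simulated.
* **Field potentials** (`simulate_field_potential()`): ~1 ms biphasic
  templates of two amplitude classes, 50 Hz hum, white noise, at a 25 kHz
  default rate (the DAQ rate is unrecorded; 25 kHz is 50x the passband
  top). Electrode drift and movement artefacts are not simulated.
* **Axon sections** (`simulate_axon_image()`): non-overlapping bright disks
  in a triangular ROI with blur and noise — count and diameter ground truth
  without myelin texture or touching axons.

Passing tests on these generators demonstrates the pipeline's internal
correctness and parameter recovery under controlled conditions; it does not
certify performance on real recordings with artefacts the generators omit.

# Tracking

`track_stack()` composes Otsu (or fixed) thresholding with polarity
correction, largest-component selection with hole filling, Zhang-Suen
thinning, longest-path pruning (graph diameter over 8-connected skeleton
pixels, Euclidean edge weights), penalized-spline smoothing of the path
(about a dozen basis functions per coordinate, enough for one body
wavelength but stiff against pixel jitter), extension of the midline to the
silhouette boundary along the end tangents (capped by the local mask
half-width, since the medial axis stops one half-width short of a blunt
end), and arc-length resampling to 51 equidistant points.

Head orientation is decided per frame by the better of two votes: the
endpoint whose offset aligns with the windowed centroid velocity (only when
the fish sustains at least 0.5 BL/s over about a second — below that, the
centroid wobble from the tail beat is pure noise), otherwise the wider end
wins (mask distance-transform averaged over the inner 5-20% band of each
end). Frame-to-frame direction is first canonicalized by endpoint proximity
so votes are comparable, then majority-filtered, which eliminates
single-frame flips. Frames that fail segmentation are flagged in the QC
table and interpolated from neighbours; more than 20% failures aborts the
run with a QC report.

On rendered wildtype cruising video (5 px/mm, 10 s at 200 fps) the full
chain recovers the tail-beat frequency within one spectral bin, the
standing-wave peak position within 0.05 BL, and per-frame tortuosity with
RMSE well under 0.03 — these are the error budgets the acceptance suite
enforces. The residual rostral bias of the recovered peak position
(~0.04 BL) comes from spline boundary flattening and the skeleton's
truncation of the head, and is stable across seeds and resolutions.

# Features

* **Tortuosity** is $(L - d)/L$ for arc length $L$ and head-to-tail
  distance $d$: 0 when straight, 1 when head and tail touch, clipped to
  $[0,1]$ after floating-point guard, invariant to rigid motion and scale.
  (An equivalent description with the opposite sign convention circulates;
  the form used here is the one consistent with the stated 0/1 endpoints.)
* **Thrust velocity** projects the centred-difference velocity onto the
  smoothed heading; summaries are medians.
* **Bending angle** is operationalized as the angle between the rostral- and
  caudal-third chords (windows configurable) — a tracker-robust proxy for
  whole-body bending with an exact oracle on circular arcs
  ($\tfrac{2}{3}\Theta$ for total turning $\Theta$).
* **Occupancy maps** are 2-D histograms normalized to percentages summing
  to 100 (mass conserved under any binning); **centre occupancy** is the
  fraction of samples in a central band of the arena's lateral extent
  (default one third — no band width is recorded for the original assay,
  and whether a band or radial criterion was used is unknown; the band is
  this package's choice).
* **Escape time series** re-zero time at the stimulus, resample individuals
  to a common grid and summarize as the cross-individual median with a
  percentile-bootstrap band.

# Electrophysiology

The filter chain mirrors the recording hardware: a zero-phase 4th-order
Butterworth band-pass (300-500 Hz) and a zero-phase notch at 50 Hz (a
software Hum Bug; Q = 10). Both run with reflection padding so edge
transients stay out of the trace; the suite checks gain >= 0.85 at 400 Hz,
<= 0.1 at 50 Hz and 1 kHz, and DC rejection below $10^{-6}$.

Spike detection thresholds at `k_mad` (default 5) times the MAD of the
filtered trace. Because a band-pass-filtered spike rings at the passband
centre, candidate events are local maxima of the *envelope* (analytic-signal
modulus), which rises once per spike; events within the 2 ms refractory
window are merged (larger wins). Detection and the two-class amplitude
split (1-D two-means on log amplitudes, deterministic quantile
initialization, unimodal inputs flagged) are normative choices of this
package, validated on simulation only — no detection or classification rule
is recorded for the original recordings, and the small/large criterion
there is unknown. Instantaneous spike frequency is the reciprocal
inter-spike interval assigned at each spike; PSTHs use bin edges anchored
at the stimulus so the t = 0 bin is exact.

# Morphometry and blinding

Axon quantification is threshold + connected components inside an arbitrary
ROI polygon, discarding specks below `min_area_px`, with equivalent diameter
$2\sqrt{\text{area}/\pi}$ scaled to um. The original analysis script's
internals are unknown; this definition is normative here and validated
against the disk generator (count exact, diameters within 5%).
`blind_labels()` maps sample identifiers to opaque sequential codes in a
seeded random order and returns the sealed inverse separately, emulating
operator blinding; the test suite checks the round trip and that codes leak
no genotype substrings.

# Statistics

* `permutation_test()`: Fisher's permutation test — group labels permuted
  without replacement (a with-replacement variant sits behind
  `replace = TRUE`), default 200,000 resamples, two-sided add-one p-value
  $p = (1 + \#\{|T^*| \ge |T_{obs}|\})/(1 + B) \ge 1/(B+1)$. The default
  statistic is the difference of group medians (the summaries reported are
  medians throughout); the difference of means is available and is used
  where large simulation grids make the median statistic too slow. A
  tolerance of $10^{-9}$ relative guards ties at $|T_{obs}|$ against
  summation-order round-off — without it, mirrored extreme splits are
  undercounted.
* `bh_fdr()`: Benjamini-Hochberg step-up adjustment (via `p.adjust`).
* `wilcoxon_rank_sum()`: exact for small samples without ties, normal
  approximation with tie correction otherwise; fully tied input returns
  p = 1 with a flag.
* `bootstrap_median_band()`: percentile bootstrap over individuals for the
  median series, seeded.

Calibration: the acceptance suite measures the permutation test's type-I
error over 2,000 null simulations (n = 10 per group, 2,000 resamples each —
scaled down from the 200,000-resample default to keep the suite fast) and
requires it inside [0.04, 0.06] at $\alpha = 0.05$.

# Numerical choices and degenerate inputs

* Arc-length resampling runs two passes of parametric spline
  re-parameterization, so consecutive spacings agree to ~$10^{-6}$ relative
  even on curved bodies.
* `steady_speed()` returns 0 exactly when there is no undulation; a bracket
  that cannot contain the thrust-drag root raises a diagnostic error rather
  than silently clamping.
* Decomposition defines 0/0 travelling index as 0 (a motionless segment is
  "not travelling").
* All generators are deterministic functions of an integer seed; pipeline
  runs write a manifest (seed, config hash, output hashes) so a run can be
  reproduced byte-for-byte.
* Problem sizes in the test and acceptance suites (10 s of 200 fps video at
  5 px/mm; 2,000 null simulations x 2,000 resamples; 10 s ephys traces) were
  chosen as the smallest sizes at which the measured quantities are stable
  against their tolerances.

# Known limitations

* The propulsion model is ordinal, not predictive: absolute speeds depend on
  the coarse drag constants, and only condition orderings and ratios are
  meaningful.
* The recoil correction is the position-level small-angle form; for the
  large bends of a C-start it is an approximation (the escape analyses do
  not use it).
* The tracker assumes a single fish, no occlusions, and roughly uniform
  background; the renderer's idealizations mean real-video performance
  must be re-validated.
* The standing/travelling decomposition assumes a single dominant
  frequency; burst-glide or multi-frequency swimming violates it and is
  flagged only indirectly through the low-power warning.
* Whether "after amino acid 86" counts the initiator methionine is
  ambiguous in the allele description; `translate_to_stop()` counts the
  initiator as residue 1 and documents it.
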