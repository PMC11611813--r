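---
title: "Analysing synthetic-larynx phonation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing synthetic-larynx phonation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonolab)
library(dplyr)
```

## The measurement problem

Bench-top phonation experiments drive a silicone replica of the larynx with
a controlled airflow while the longitudinal tension of the synthetic vocal
folds is adjusted through embedded fibers stretched by a known length.
Three channels are recorded per measurement: high-speed video of the
glottis (thousands of frames per second), the acoustic signal radiated
above the model, and the subglottal pressure beneath it. From these,
fifteen phonation parameters are computed per measurement — two general
ones (fundamental frequency F0 from the pressure trace, mean subglottal
pressure Psub), nine glottal-area-waveform (GAW) parameters (amplitude and
time periodicity AP/TP, amplitude symmetry and phase asymmetry ASI/PAI,
glottal gap index GGI, closing quotient ClQ, maximum area declination rate
MADR, the stiffness parameter, and the amplitude-to-length ratio ALR), and
four acoustic ones (cepstral peak prominence CPP, harmonics-to-noise ratio
HNR, local jitter and shimmer). The two experimental factors — flow rate
(standard liters per minute, SLM) and fiber stretching length (mm) — are
then tested for their influence on every parameter with Kruskal-Wallis
screening and Mann-Whitney post hoc tests under Bonferroni correction.

phonolab implements this entire chain, together with a kinematic
oscillation simulator that generates recordings with *known* ground truth,
so every estimator in the chain can be validated quantitatively without
access to laboratory data.

## The kinematic oscillator

`oscillator_spec()` parameterises one synthetic recording. Each fold's
medial edge opens as a rectified sinusoid above a prephonatory half-gap:

$$ w_{\mathrm{side}}(t) \;=\; \max\{0,\; g + a_{\mathrm{side}}\, m(t) \sin \varphi_{\mathrm{side}}(t)\} $$

with $g$ the half-gap (px), $a$ the lateral half-amplitude (px), and the
right fold delayed by `phase_offset_frac` of a period. The hemiglottal
area is `glottal_length` times the open width; the total GAW is the sum of
the two sides. Two regimes follow directly from the geometry: when
$g > a$, the folds never touch and the glottis stays open throughout the
cycle (incomplete closure, GGI $=(g-a)/(g+a) > 0$); when $a \ge g$, the
folds collide and a closed phase appears (GGI $= 0$). Both occur in real
silicone-model recordings, and all estimators are required to behave
consistently across the two regimes.

This model is deliberately kinematic rather than dynamical (no lumped
masses, no flow-structure coupling): every parameter the analysis chain
measures is a kinematic quantity, so a kinematic generator provides exact
closed-form ground truth — e.g. for a pure sinusoid $A(t) = A_0 + a\sin(2\pi f t)$
the stiffness parameter (the per-cycle maximum of $|dA/dt|$ over the
cycle's dynamic range) is exactly $\pi f$, and MADR is exactly $2\pi f a$.
The test suite pins both to within 0.5%.

### Cycle-to-cycle perturbation

Perturbation is modelled with independent lognormal multipliers on each
cycle's period and amplitude, calibrated in closed form so the *expected
local* jitter/shimmer (mean absolute difference of successive cycles over
the mean) equals the requested percentage: for a target of $j$%, the
lognormal sigma solves $2(2\Phi(\sigma/\sqrt2)-1) = j/100$. Independent
multipliers (rather than an autoregressive process) match the "two
succeeding cycles" definition of the local measures being validated.

The amplitude multipliers are realized as a piecewise-constant track with
a short cosine cross-fade (20% of a period) between cycles. The fade is
placed away from the waveform feature that carries the cycle's amplitude —
on the descending limb for the GAW, mid-cycle for the acoustic pulse train
— so the measured per-cycle amplitude equals the cycle's factor exactly
and the waveform has no step discontinuities. A hard switch at the cycle
boundary would sit exactly on the trough (or on the acoustic pulse) and
corrupt boundary timing and peak amplitudes; this placement was chosen
after observing exactly that failure mode.

### Audio and pressure channels

The audio source is a harmonic pulse train (8 harmonics, 1/k roll-off) on
the perturbed phase track, plus white noise rescaled so the realized
harmonic-to-noise power ratio equals `hnr_target` exactly. The model
radiates into free field, so no vocal-tract filter is applied. The
pressure trace is the mean pressure plus a ripple at F0 plus noise,
recentred so its sample mean equals `psub_mean` exactly.

## The analysis chain

### Cycle detection

F0 is pre-estimated from the normalized autocorrelation of the
mean-removed GAW within 60–880 Hz (covering the plausible oscillation
band with margin), with parabolic lag interpolation and an octave guard:
the smallest lag whose local maximum reaches 90% of the band maximum wins,
since strong shimmer otherwise promotes the 2T subharmonic and halves the
detected cycle count. The series is lightly smoothed (Savitzky-Golay,
order 3, window ≈ one tenth of a period, minimum 5 frames — chosen because
it passes low-order structure essentially undistorted where a moving
average of the same width would already attenuate the waveform by over
1%). Cycle boundaries sit at the minima between successive upward
crossings of the 50%-of-range level; the boundary position is refined to
sub-frame precision as the centre of the near-minimum region, timed from
its two threshold crossings — for a sharp trough this is the minimum, for
a flat closed phase its midpoint, and both are stable against smoothing
ripple where a plain argmin is not. All per-cycle quantities (durations,
extrema, peak times, derivative maxima) are measured on a dense cubic
spline (16x oversampling), so parameters do not inherit the video frame
quantisation; at 4000 fps vs 8000 fps the parameters agree within 1%.

A minimum of 20 cycles is enforced for waveform parameters and 100
detectable cycles for jitter/shimmer; shorter inputs raise typed errors
carrying the detected count. Flat signals raise a no-oscillation error;
flat-topped cycles where the post-peak minimum is ambiguous resolve to the
earliest minimum.

### Cycle amplitude: two estimators, two jobs

The per-cycle *dynamic range* (max − min) is the authoritative amplitude
for GGI, the stiffness parameter, ALR and MADR — the closed-form
identities above depend on it. For the *ratio-based* indices (AP, ASI),
however, the dynamic range has a closure-regime-dependent flaw: in a
non-closing oscillation the cycle minimum is a trough shared with the
neighbouring cycle, so the deeper of the two flanking troughs leaks into
each cycle's range and damps the measured cycle-to-cycle variation by
roughly a factor of two — while fully-closing cycles (minimum pinned at
zero) are unbiased. A simulated experiment in which tension closes the
glottis then shows a spurious tension effect on AP that the generator
never encoded. AP and ASI therefore use the *oscillatory amplitude*
`a_osc` — peak height above the cycle's own starting trough — whose
consecutive ratios track the true amplitude perturbation uniformly in
both regimes (exactly so on the kinematic model). Both columns are
reported by `detect_cycles()`.

### Closing quotient: two readings

The parameter's verbal definition ("time with full glottal closure") and
its categorisation ("0 = full closure") conflict, so both readings are
implemented and selectable: the default closing-quotient reading (time
from cycle peak to the following minimum over the cycle duration; 0.5 for
a symmetric oscillation) and a closed-phase reading (fraction of the
cycle with area at or below 2% of the cycle maximum). Neither is asserted
as "the" published definition.

### Acoustic measures

Jitter and shimmer are the local variants: cycle marks come from
period-synchronous peak picking (seeded by the autocorrelation F0, local
maxima within ±45% of the predicted period, sub-sample refinement on a
local spline), then mean absolute consecutive differences over the mean,
in percent. On noise-free synthetic audio the residual floor is below
0.001 percentage points, and across 20 seeds at 100+ cycles the mean
recovery bias is within ±0.3 points of the generator targets. Additive
noise rides on the interpolated peaks and inflates peak-based shimmer (by
about +0.5 points at 30 dB HNR) — an inherent property of the estimator,
which is why the recovery claim is made on noise-free signals.

CPP follows the common cepstral convention: per 40 ms Hann window (50%
overlap), the cepstrum is the dB power of the Fourier transform of the dB
log-power spectrum; a regression line of cepstrum on quefrency over the
1/880–1/60 s band is subtracted from the cepstral peak, and windows are
averaged. Since the cited smoothed variant is never specified precisely,
the plain window-averaged CPP is the default; an independent explicit-DFT
oracle in the test suite agrees to 0.1 dB. HNR uses the window-normalized
autocorrelation maximum at the fundamental lag, $10\log_{10}(r/(1-r))$,
capped at +40 dB to keep noise-free signals finite; generator targets in
5–30 dB are recovered within ±1.5 dB.

F0 and Psub come from the pressure trace (its mean, and the
autocorrelation peak refined parabolically); a trace whose best in-band
autocorrelation peak is below 0.3 is declared unvoiced, with the mean
pressure still attached to the error condition.

### Segmentation of frame stacks

`segment_frames()` re-implements the minimal glottis-segmentation chain:
optional Gaussian smoothing, Otsu thresholding on the histogram pooled
over the whole stack (per-frame thresholds would wander on nearly-closed
frames), largest connected component above 20 px (rejecting texture
speckles), with an all-background guard (if thresholding lights up over a
quarter of all pixels, the stack is treated as gap-free, with a warning).
The midline direction is the first principal axis of the gap pixels
pooled over the stack — pooling prevents left/right label flips when the
gap nearly closes — anchored on the line through the two glottal
commissures (the pooled extreme tips along the axis). The anchor matters:
the pixel *centroid* shifts toward the stronger fold under amplitude
asymmetry and would equalise the measured halves. Rendered gaps of
analytic area ≥ 500 px² are recovered within 2% and symmetric renders
split left/right within 1%.

One limitation is intrinsic: when the glottis never closes, the anatomical
contact line is not observable in any frame, so every data-driven midline
carries a sub-pixel bias proportional to the asymmetry itself, biasing
segmentation-derived ASI toward 1. Frame-derived and directly generated
waveforms agree within 3% on the scale and shape parameters (AP, TP, GGI,
ClQ, MADR, stiff); ASI from segmentation should only be trusted for
recordings with (near-)complete closure.

`render_frames()` is the inverse path used to validate segmentation: a
lens-shaped gap between two opposed parabolic edges whose half-width
profile is normalised so the painted (coverage-weighted) area equals the
waveform's area exactly, anti-aliased analytically, on a noisy darker
background.

## The simulated experiment

`default_experiment_grid()` spans 76 (flow, stretch) conditions: flows
drawn exactly from the four canonical flow-group value sets (FG1:
30–40 SLM, FG2: 50–80, FG3: 90–120, FG4: 130–200) with group counts
18/18/20/20, over five stretching lengths 0–20 mm. The published design
fixes only those group counts, not the pairing, so the pairing is a
package default chosen on two grounds: the onset flow is non-decreasing
with stretch (higher-tension states start oscillating at higher flows, as
in the measurement protocol), and the mean flow per stretch level stays
approximately balanced (93–99 SLM), so the grid itself induces no
artificial stretch-to-pressure confound.

`default_response_coefficients()` encodes the qualitative responses the
simulator is meant to reproduce, each configurable:

* `psub = 200 + 14·flow` Pa — the linear flow-pressure relation
  (620–3000 Pa over 30–200 SLM, the order of magnitude of such models);
* amplitude rising and saturating with flow, `40·flow/(flow+60)` px;
* `f0 = 220 + 120·min(stretch,10)/10` Hz — rising with tension and
  saturating above 10 mm, spanning 220–340 Hz;
* half-gap `90·max(0, 1−stretch/10)` px — incomplete closure at low
  tension, complete closure from 10 mm on;
* harmonicity (HNR target) improving with both flow (logarithmically) and
  stretch; jitter/shimmer declining mildly with stretch;
* an amplitude-instability band for mid-range flows (45–85 SLM) that
  inflates shimmer by a uniform 1.3–2.3 factor — reproducing the one flow
  group with visibly degraded amplitude periodicity;
* condition-to-condition lognormal variability on F0 (2%), amplitude
  (5%), asymmetry targets (3% and 20%), HNR (1.2 dB), and a deliberately
  wide 70% on the perturbation targets, mirroring the wide periodicity
  spread real recordings show.

With these defaults the two significance reports reproduce the
experiment's qualitative pattern: the flow design flags Psub, MADR and
ALR (the pressure/amplitude-driven parameters), the stretch design flags
F0, GGI, stiff and CPP (the tension-driven ones) while leaving Psub, AP,
TP, ASI and PAI non-significant. This pattern is asserted end-to-end in
the test suite at a fixed seed and holds across seeds; parameters with no
encoded effect still show chance significance at the nominal 5% screening
rate, exactly as a correctly calibrated test should.

What the generator does *not* emulate: fluid-structure interaction and
aerodynamics, vocal-tract/room acoustics, real endoscopic artifacts
(specular highlights, motion blur), mucosal-wave kinematics beyond the
medial edge, and any pixel-to-physical calibration (areas stay in px²;
MADR is reported per Mpx for scale). Passing tests therefore validate the
estimators and the statistical machinery, not the physics of any
particular larynx model.

## The statistical design

Measurements are grouped into FG1–FG4 by exact membership in the flow
value sets (out-of-set flows fall to the nearest boundary, with a
warning), and stretching lengths are compared pairwise in canonical order
(0–5, 0–10, …, 15–20 mm). Per parameter, a Kruskal-Wallis test (tie
corrected, chi-square approximation) screens at p < 0.05; only then are
two-sided Mann-Whitney U tests run per pair, exact by enumeration when
the combined sample is ≤ 16 without ties and via the tie-corrected normal
approximation otherwise (group sizes here, 13–20, straddle that
boundary; the method used is recorded per cell). The Bonferroni levels
are recomputed from the design — 0.05/6 ≈ 0.0083 for the four flow
groups, 0.05/10 = 0.005 for the ten stretch pairs — and displayed at 4
decimals. Pairs of parameters that fail the screening test are reported
as *skipped*, mirroring the dash convention of the published summary
tables; whether the original analysis ran (and merely omitted) those
tests is unknowable from the dashes, so skipping is the package's
interpretation. A null simulation (1000 replicates) confirms the gated
procedure keeps the family-wise false-positive rate at or below 0.05.

Boxplot summaries use linear-interpolation quartiles (R type 7; Tukey
hinges would move whiskers slightly), whiskers at the most extreme points
within 1.5 IQR, means marked separately — the convention used for the
experiment's figures.

## Problem sizes and runtime choices

The shipped defaults are sized for interactive use and continuous
testing: 40-cycle waveforms per condition (twice the 20-cycle minimum),
1 s of audio (at least 100 cycles at any simulated F0, matching the
100-cycle acoustic convention), 1 s of pressure, 76 conditions per
simulated experiment (a full pipeline run takes well under a minute), and
frame stacks only where the imaging path itself is under test (a few
hundred 192–256 px frames). Every stochastic entry point takes an
explicit seed and derives per-condition seeds from it; the same seed
reproduces every downstream number bit for bit, and the run manifest
records seed and coefficients.

## Known limitations

* ASI from segmentation is biased toward symmetry for never-closing
  recordings (midline unobservability, above).
* Peak-based shimmer inflates with additive noise; compare shimmer values
  only across recordings of comparable HNR.
* The closing-quotient default reading is one of two defensible
  interpretations; switch to the closed-phase reading via
  `clq_method = "closed_phase"` where that is the intended quantity.
* The simulator's responses are qualitative encodings, not fitted physics;
  absolute parameter values should not be compared against any specific
  laboratory dataset.
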