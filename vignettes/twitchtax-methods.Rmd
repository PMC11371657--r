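---
title: "Models and methods behind twitchtax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind twitchtax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twitchtax)
```

## The scientific problem

Surface-attached *Pseudomonas aeruginosa* cells move by twitching: type IV
pili extend from a cell pole, attach, and retract, dragging the rod-shaped
body across the surface at about 0.2 µm per minute. The retraction motor
(a PilT fluorescent fusion in the experiments this package models)
accumulates at the leading pole, so the sub-cellular position of the fusion
protein reports which pole a cell treats as its front — even while the cell
is stationary. When a chemoattractant gradient across the cell flips
direction, a stationary cell may *repolarize*: re-localize the motor to the
pole now facing higher concentration and, often, move off in that
direction. The relative frequency of repolarizations toward versus away
from the gradient separates two hypotheses about how such slow cells sense
gradients: purely *temporal* sensing (concentration changes over time
carry no directional information for a stationary cell, so both directions
should be equally frequent) versus *spatial* sensing (a concentration
difference across the ~2–4 µm body picks the correct pole more often than
not).

`twitchtax` implements the full computational side of this assay:
microfluidic gradient models and their design arithmetic, cell detection
and tracking, trajectory kinematics and motility classification,
longitudinal fluorescence profiling and polarity classification, the
rule-based repolarization event classifier, and the exact count statistics.
Because the raw imaging data behind such experiments are hundreds of
gigabytes and not generally redistributable, the package also contains a
first-class synthetic microscopy generator with complete ground truth; all
validation rests on it.

## Gradient models

Three microfluidic geometries are modelled by `concentration_field()` and
reported on by `design_report()`. All concentrations are in mM, lengths in
µm, times in minutes.

**Dual-flow (Y-channel) gradient.** Two co-flowing streams, one carrying
the chemoattractant at concentration $C_{source}$, mix by molecular
diffusion across the channel. `dualflow_profile()` uses an error-function
profile

$$C(y) = \frac{C_{source}}{2}\left(1 + s\,\mathrm{erf}\!\big(\sqrt{\pi}\,(y - y_{mid})/w\big)\right),$$

with epoch sign $s = \pm 1$ flipping the orientation. The $\sqrt{\pi}$
factor normalises the slope so that the mid-channel gradient is exactly
$C_{source}/w$: with the reference values $C_{source} = 2$ mM and
$w = 100$ µm this reproduces the working spatial gradient of
0.02 mM µm⁻¹. A cell moving at $V_C$ through a static spatial gradient
manufactures its own temporal stimulus $dC/dt = V_C\,dC/dx$
(`temporal_gradient_from_motion()`); at $V_C = 0.2$ µm min⁻¹ this is
0.004 mM min⁻¹.

**Taylor–Aris dispersion front.** A solute front pre-stretched by
shear-enhanced dispersion in a long inlet tube and advected past the cells
at the mean flow speed $U$. `taylor_aris_front()` uses the same erf shape,

$$C(x,t) = C_{min} + (C_{max}-C_{min})\,S\!\big((x-Ut)/L\big),\qquad
S(z) = \tfrac12\big(1+\mathrm{erf}(\sqrt{\pi}z)\big),$$

the long-time similarity solution of one-dimensional
advection–dispersion. Only the endpoint concentrations and the length
scale are treated as empirical anchors; $L$ is defined so that
$(C_{max}-C_{min})/L$ equals the mid-front spatial gradient, which makes
the quoted design numbers literal properties of the model field. With
$C_{max}=1.16$, $C_{min}=0.84$, $\tau = 60$ min and
$U = 27{,}000$ µm min⁻¹: $dC/dt \approx 0.005$ mM min⁻¹,
$L = U\tau \approx 1.6$ m, $dC/dx \approx 2\times10^{-7}$ mM µm⁻¹ —
a gradient roughly 16,000-fold longer than the dual-flow one while
delivering the same mean temporal stimulus. No molecular diffusion
coefficient enters any reported number, so none is a model parameter.

**Medium switching.** Abrupt exchange of the whole medium, smoothed over a
transition timescale $\tau$. `switching_profile()` uses a $C^1$ sinusoidal
smoothstep that starts and completes exactly $\tau/2$ before and after the
switch. We chose this over an erf ramp deliberately: the transition then
finishes in finite time, and the mean $|dC/dt|$ over the ramp is exactly
$(C_{max}-C_{min})/\tau$ — 0.213 mM min⁻¹ (printed 0.2) at
$\tau = 1.5$ min — so the design arithmetic again describes the model
field without a shape-dependent fudge factor. The associated spatial
gradient over the test section, $(C_{max}-C_{min})/(U\tau)$, is
$8.5\times10^{-5}$ mM µm⁻¹.

`dye_to_concentration()` inverts the affine dye calibration (the
visualisation dye responds linearly to concentration), clipping to the
physical range with a warning.

## The synthetic microscopy generator

`scenario_config()` + `simulate_experiment()` emulate the study
conditions:

* **Motion.** Motile cells translocate along their body axis at a mean
  speed of 0.2 µm min⁻¹, with single-frame jumps 20× faster (rare pilus
  release events, default probability 0.01 per frame), and direction
  reversals as a Poisson process (default 0.005 min⁻¹, i.e. one reversal
  every few hours). A configurable fraction of cells (default 7.5%, the
  middle of the observed 5–10% range) is stationary, moving only by
  Gaussian sub-pixel jitter (σ = 0.02 µm per frame) chosen to exercise,
  without crossing, the stationarity thresholds.
* **Acquisition.** Two channels share one clock: the cell (brightfield-
  like) channel at 7.5 frames min⁻¹ and the fluorescence channel at
  0.5 frames min⁻¹ (the experiments used 0.4–0.5; we fix 0.5 so that the
  rate ratio is an integer and every fluorescence frame coincides with a
  cell-channel frame). Frames cover the half-open interval
  $[0, \mathrm{duration})$.
* **Appearance.** Cells render as soft-edged spherocylinders (the simplest
  shape with well-defined poles and aspect ratio); the fluorescence
  channel adds a dim uniform body plus isotropic Gaussian foci
  (σ = 0.15 µm) at the bright pole(s), optionally offset laterally to
  exercise the multi-line profiler; the dye channel is an affine map of
  the analytic concentration field. Pixel size defaults to 0.1 µm/px — an
  ordinary 100× configuration; no optical calibration is inherited from
  any particular instrument. Noise defaults to none in tests; Gaussian
  and Poisson models are available.
* **Polarity timelines.** Each cell carries a scripted per-fluorescence-
  frame polarity class. Stationary cells draw a persistent class
  (nonpolar 30%, unipolar 55%, bipolar 15% — proportions of the kind seen
  in stationary populations); motile cells are unipolar with the bright
  pole at the leading pole with probability 0.84, matching the observed
  leading-pole localization bias. Timelines change *only* at scripted
  repolarization events. This is the one deliberately unrealistic
  simplification: real localizations flicker and occasionally relocate
  spontaneously. It buys a structural guarantee — an event-free run
  contains no event signal at all — so closure tests separate detector
  errors from generator noise. What passing closure shows is therefore
  that the rules fire exactly when their preconditions occur, not that
  spontaneous fluctuation can never mimic an event on real data (the
  experiments handled that with manual curation, which we do not model).
* **Placement.** Cells are placed on a jittered grid and each cell's
  centroid reflects within its own tile, so bodies from neighbouring
  tiles can never approach the profiler's sampling band. The synthetic
  monolayer is thus solitary by construction — the population the
  repolarization assay targets; dense clusters, cell–cell mechanics and
  neighbour fluorescence contamination are out of scope (the experiments
  excluded clustered cells by filtering and manual inspection).
* **Scripted events.** A `repolarization_spec()` row (cell, fluorescence
  frame, correct?) forces that cell stationary, aligns it within ±0.3 rad
  of the gradient axis, draws an initial class that does not trip the
  detector's veto, and switches it to a sustained unipolar class at the
  event frame, at the up-gradient pole for correct events (resolved
  against the analytic field at the event time) and the down-gradient
  pole otherwise.

Determinism: a configuration plus seed reproduces every table and frame
bit-for-bit; per-cell and per-frame seeds are derived so that rendering
order does not matter.

## Cell detection and kinematics

`segment_frame()` thresholds (default midway between image minimum and
maximum — adequate for clean synthetic frames; config-exposed for anything
else), labels connected components, and estimates each pose from image
moments: centroid, principal-axis orientation, and length/width as extents
along/across that axis. `link_tracks()` uses greedy nearest-neighbour
assignment with no gap tolerance and a 2 µm/frame step limit — appropriate
at synthetic densities where a linear-assignment tracker would be
overkill. `filter_cells()` applies the two object filters used before any
polarity analysis: no appreciable reporter fluorescence (detritus;
default threshold 3× background median) and aspect ratio below 1.4 (cells
not flat on the surface); the 1.4 boundary is inclusive on the keep side,
since it is the sub-1.4 cells that are omitted.

Kinematics per track: speeds from finite differences; the net-to-gross
displacement ratio (NGDR) over the full track; orientation unwrapped from
its axial (mod π) range and smoothed with a first-order Savitzky–Golay
filter over a 20 min window; angular velocity by central differences of
the smoothed series. `classify_motility()` applies, in order: mean speed
below 0.038 µm min⁻¹ → stationary (the mean, rather than a windowed
statistic, is our reading of an unspecified choice — full-track NGDR
likewise); NGDR < 0.04 → excluded as jostling; smoothed |angular velocity|
above 0.073 rad min⁻¹ for a contiguous period longer than 2 min →
excluded as rotating; otherwise motile.

`detect_reversals()` is a documented stand-in for an upstream tracking
suite's unpublished reversal detector: a reversal is logged where the
dominant displacement directions over the preceding and following
2-frame windows differ by more than 150°, with detections within the
persistence window merged. Both parameters are config-exposed; on scripted
tracks the defaults give recall and precision above 0.95.

## Polarity profiling and classification

For each cell and fluorescence frame, `sample_longitudinal_profile()` lays
10 parallel lines with the cell's orientation and length, spaced 0.09 µm
apart so they span about one cell width (~0.9 µm), samples them by
bilinear interpolation at one-pixel arclength intervals, and takes the
across-line maximum at each arclength — robust to foci sitting off the
centreline and to small movement between channel acquisitions.
`pole_metrics()` takes raw maxima over the two pole windows (each one
tenth of the cell length), the mean over the central quarter, and
normalised pole intensities $I_1, I_2$ (pole maximum / mid-cell mean).

`classify_polarity()` applies rules in a fixed order (the source
procedure lists them without an explicit ordering; exclusion → thresholds
→ reassignment is the order that prevents a division signal from ever
being read as polar):

1. *Mid-cell exclusion*: if the mid-cell mean exceeds both raw pole maxima
   the cell is nearing division (machinery accumulates at the nascent
   mid-cell poles) and is excluded. A 5% relative margin guards the
   comparison: on a focus-free cell the pole window of a short cell sits
   partly in the soft intensity falloff at the tip, so its maximum runs a
   few percent below the body plateau and a strict comparison would flag
   flat cells on sampling noise. Genuine division signals exceed the pole
   values many-fold and are unaffected.
2. *Thresholds* (strict inequalities): both $I > I_{min}$ → bipolar,
   exactly one → unipolar at that pole, neither → nonpolar.
3. *Reassignment*: a bipolar call whose pole ratio
   $\max(I_1,I_2)/\min(I_1,I_2)$ exceeds `ratio_max` becomes unipolar at
   the stronger pole.

The numeric thresholds were chosen by visual inspection in the source
experiments and never published; `calibrate_thresholds()` is an automated
stand-in that places $I_{min}$ at the anti-mode of the pooled
pole-intensity distribution and `ratio_max` at the anti-mode of the
log pole-ratio distribution, returning the pooled data for operator
review and falling back to defaults (2 and 3) with a warning when a
distribution is effectively unimodal. Mode detection requires the
secondary mode to be at least half a standard deviation from the primary
and 5% of its height, so jitter within one cluster is not mistaken for
structure.

## Repolarization events

`gradient_timeline()` fixes the epoch bookkeeping: swap times, per-epoch
gradient signs (starting +1), both frame clocks, and a centreline dead
zone of half-width $0.1 w$ (the experiments excluded near-centreline
cells without publishing a cutoff; one tenth of the gradient length scale
is where the concentration change at a swap falls below ~30% of its
asymptotic value). All distances are measured along the gradient axis.

For each cell and swap, `detect_event()`:

* assigns the **initial polarity** as the majority mode over the four
  fluorescence frames preceding the swap, a 2–2 tie going to the frame
  immediately before; mid-cell exclusions are never counted as polar
  signal, and when a division flag occurs only frames after it count
  (with the event marked post-division);
* **vetoes** any pole that was already unipolar in ≥2 of those four
  frames or in the frame immediately preceding the swap;
* scans the epoch for **trigger A** (a unipolar class at a non-vetoed
  pole holding in ≥2 of the 4 consecutive fluorescence frames starting
  there) and **trigger B** (two consecutive same-direction cell-channel
  steps of at least one cell width each along the gradient axis —
  "consistent direction" read as same-sign steps, and the nominal 0.9 µm
  width used rather than each cell's measured width, both config-exposed);
  trigger A runs on the fluorescence clock, trigger B on the cell-channel
  clock, and event frames are reported on the cell-channel clock;
* accepts the earlier trigger that also passes
  `stationary_window_check()`: from the frame after the last frame of the
  initial gradient to the event frame (at least 3 frames before it), the
  cell must neither move more than half a cell width in the same
  direction on two consecutive frames nor stray more than one cell width
  from its starting position, all along the gradient axis.

`classify_correctness()` compares the analytic concentration at the two
pole positions at the event time; `assign_temporal_change()` classifies
the pre-swap concentration at the cell against $C_{max}/2$ (step-up /
step-down), with the dead zone giving `not_assignable`.
`summarize_events()` tabulates correct vs incorrect overall and by
initial polarity and temporal change, with Wilson intervals and exact
binomial tests against equal abundance.

## Count statistics

Reversals are rare relative to trajectory points, so counts are treated
as Poisson with points as exposure: `poisson_rate_ci()` gives the exact
(Garwood) gamma-quantile interval; `exact_poisson_two_sample()` the
conditional exact test (given $N = n_1+n_2$, $n_1$ is binomial with the
exposure share as success probability); `exact_binomial_test()` the exact
binomial test with the minimum-likelihood two-sided convention;
`proportion_ci()` the Wilson score interval (the interval method behind
published error bars is unstated; Wilson is our documented choice, exact
at the $k=0$ and $k=n$ endpoints and well-behaved at small counts).
These delegate to the corresponding exact routines in base R's stats
package — the same implementations a practitioner would call — and the
test suite cross-checks every one against independent brute-force
enumeration and closed forms, plus Monte-Carlo coverage at the study's
operating points ($\lambda = 100$; $p = 0.85$, $n = 171$).

## Problem sizes and numerical choices

The validation suite runs everything at desk scale, chosen as the
smallest sizes at which each property is statistically meaningful: the
end-to-end closure run uses 200 cells for 90 min (one gradient swap,
24 scripted events, 45 fluorescence frames on a 204.8 µm field); the
polarity-recovery run 150 stationary cells for 60 min; coverage checks
use 10⁴ replicates; the type-I control of the reversal-rate comparison
uses 10³ runs of 90,000 trajectory points at a reversal probability of
0.0032 per point (the empirical order of magnitude). Determinism,
tie-breaks and degenerate inputs are handled explicitly: axial angles are
unwrapped before smoothing; zero gross displacement defines NGDR = 0;
single-frame tracks are classed stationary and excluded from rate
denominators; empty intervals report undefined rates; equal pole
concentrations make correctness unclassifiable rather than arbitrary.

## Known limitations

* The generator does not model photobleaching, drift, uneven
  illumination, cell division, cell–cell contact or neighbour
  fluorescence contamination; closure results bound detector correctness,
  not robustness to those effects.
* Spontaneous (gradient-independent) repolarizations are real but
  unscripted here; on real data they would appear as a basal event rate
  in both directions.
* The reversal detector is a stand-in with its own parameters, not a
  reimplementation of any published tracker's internals.
* Polarity thresholds calibrated by anti-modes assume a reasonably
  bimodal intensity population; sparse or all-nonpolar data fall back to
  defaults with a warning rather than failing.
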