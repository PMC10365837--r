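---
title: "Quantification methods in axonquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods in axonquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonquant)
```

axonquant packages the measurement machinery used to quantify presynaptic
physiology in reconstituted corticostriatal networks: axonal transport of
synaptic vesicle precursors (SVPs), pHluorin-reported exocytosis, electron
microscopy (EM) morphometry of presynaptic terminals, puncta colocalization,
paired-pulse electrophysiology, and the statistical decision workflow that
ties the readouts together. Because the raw recordings behind such studies
are rarely deposited, every analysis stage here is paired with a seeded
simulator that generates inputs with exported ground truth; the test suite
exercises each stage against that truth.

This vignette explains the models, the parameters that matter (with units
and defaults), the numerical choices, and what the simulations do and do not
establish about real data.

## Axonal transport from time-lapse movies

**Acquisition model.** Movies are imaged every 200 ms for 1 min (300
frames), the standard protocol for SVP transport in microfluidic devices,
over a 100 µm axon window at 0.1 µm/px (a 63x objective scale; the pixel
size is configurable because instruments differ). The axial coordinate runs
from the soma end toward the presynapse, so anterograde displacement is
positive everywhere in the package.

**Vesicle kinematics.** Each vesicle is a three-state (anterograde,
retrograde, paused) continuous-time Markov chain sampled at the frame
interval, with a per-vesicle segmental speed drawn at each state entry
(defaults: anterograde 1.2 ± 0.2 µm/s, retrograde 1.0 ± 0.2 µm/s — typical
fast-transport speeds for VAMP2-class cargo). A configurable static fraction
(default 0.2) never moves. Default switching hazards are 0.06–0.1 /s, i.e.
a state change roughly every 10–15 s. Vesicles that reach either end of the
window leave the field, as they do in real recordings. Spots are rendered as
Gaussians (σ = 1.3 px) on a flat background with Poisson noise by default
(Gaussian and noise-free modes exist for analytic checks). With the default
background (100 photons) and amplitude (120 photons) the peak signal-to-noise
ratio is ≈ 8.

**Kymographs.** `extract_kymograph()` resamples the axon path at one bin
per pixel and takes the maximum intensity across the path's transverse
width, producing the classic space–time image in which line slope encodes
velocity. The kymograph is the visualization/QC artifact; quantification
runs on tracks.

**Detection and tracking.** `detect_and_link()` detects spots per frame as
local maxima of a difference-of-Gaussians (DoG) response, refines them to
sub-pixel centroids, and projects them to arc length. Two vesicles closer
than about 2.5 px along the axon merge into a single detection — the
occlusions that dominate tracking errors. Linking is nearest-neighbour against a
constant-velocity prediction (windowed over the last few frames so a single
corrupted position does not derail it), gated at `max_link_step` (default
0.6 µm/frame, i.e. 3 µm/s). Three mechanisms deal with the crossings and
co-travelling pairs that dominate errors at realistic densities: occluded
tracks *coast* on their motion model while their prediction still overlaps a
detection (coasted positions are bookkeeping, never measurements, and are
dropped from the returned tracks); broken fragments are *stitched* when one
end's extrapolation meets the other within a gap-scaled tolerance; and tail
*swaps at crossings* are undone whenever exchanging the two tails reduces
the velocity discontinuity. These heuristics are evaluated honestly against
simulator truth (see the package tests): identity errors concentrate where
several vesicles interact at once, which no position-only tracker can fully
disambiguate.

**Segmental motion and per-axon metrics.** `segment_track()` labels each
frame-to-frame interval anterograde/retrograde/paused (pause threshold
0.1 µm/s), merges runs shorter than `min_segment_frames` (default 3) into
their longer neighbour, and scores each segment's mean unsigned speed as
|net displacement| / duration. `classify_vesicle()` calls a vesicle static
when its maximal excursion stays below 0.4 µm (≈ the localization noise
floor at the default pixel size) and otherwise assigns the direction with
the larger cumulative displacement, breaking exact ties toward the
later-occurring direction. `summarize_axon()` then reports, per 100 µm
window and 1 min of recording: mean segmental anterograde and retrograde
speeds (over segments of all tracks), counts by class, **net directional
flux** = (n~antero~ − n~retro~) per 100 µm per min (a count difference, per
the way vesicle numbers are reported in this field), **linear flow** =
summed signed net displacement per vesicle per minute, and
**directionality** = (D~antero~ − D~retro~)/(D~antero~ + D~retro~) on
cumulative segmental displacements, reported as missing when nothing moves.
Linear flow and directionality are explicit reconstructions — the field's
usage delegates their formulas to earlier work — and are pinned down by
sign/symmetry properties in the tests (both flip sign under mirror
reflection of the axial coordinate).

## Exocytosis events in pHluorin movies

Each field is acquired four times (one acquisition before and three after
stimulation). `detect_events()` averages each synapse ROI (a disc) per
frame, subtracts a *trailing* rolling-median baseline (25 frames = 5 s;
trailing rather than centred so a step rise is measured against
pre-event baseline only, making the noise-free peak ΔF exactly the injected
amplitude), and calls an event wherever the baseline-subtracted trace
sits above `dF_threshold` *and* has risen by at least the threshold within
the last three frames — a genuine step, so a second fusion landing on the
decaying tail of the first is counted while noise wobbling around the
threshold during a decay never re-triggers. Successive events in one ROI
respect a dead time of `min_separation` frames (default 3, i.e. 0.6 s).

`tally_field()` aggregates the three post-stimulation acquisitions by
*mean* (not sum), keeping pre and post on the same per-acquisition scale.
`normalize_activity()` computes the normalized activity of test field *i*
with post-minus-pre change Δ~i~ against reference-field changes x~1~…x~n~:

$$y_i = \frac{(\Delta_i - \bar{x}) + 100}{100}$$

so a test field whose activity increased exactly as much as the average
reference field scores exactly 1. The statistic is affine in Δ~i~ with slope
1/100, and reference fields normalized against their own mean average to 1;
both identities are asserted in the tests. `normalize_amplitude()` divides
each synapse's post-stimulation mean peak ΔF by the same synapse's
pre-stimulation value.

## EM morphometry of presynaptic terminals

Annotations are consumed as coordinates in nm: a terminal outline polygon,
an active-zone polyline along the PSD-facing membrane, and vesicle
centroids (vesicle identification from raw micrographs is upstream manual
annotation; a radius field is retained for an optional edge-distance mode).
`terminal_area()` is the shoelace area (µm²); densities are counts per µm²,
and synapse density is counted on axon-free neuropil and expressed per
100 µm².

`partition_zones()` builds three 40-nm-wide zones by Euclidean distance to
the active zone — boundaries at 40, 80 and 120 nm — as Clipper buffer
differences around the polyline clipped to the terminal; zone areas are
shoelace areas of the clipped rings (Monte-Carlo rejection sampling is the
independent oracle in the tests, agreeing within 1 % at 10⁶ samples).
`assign_vesicles()` puts each centroid in the half-open band [(k−1)·40,
k·40) containing its distance — half-open so boundary ties resolve
deterministically; a centroid at exactly 0 nm is zone 1 — with centroids
beyond 120 nm labelled `beyond` and centroids outside the terminal excluded
with a warning. Zone assignment is invariant under rigid motions and the
per-zone counts plus `beyond` plus `excluded` always sum to the input count.

The simulator draws terminals as radially perturbed ellipses (600 × 360 nm
by default) with the active zone along 30 % of the boundary, and places
vesicles by rejection sampling within the requested band with a hard-core
constraint of one vesicle diameter (synaptic vesicles do not
interpenetrate). The default zone mix (0.12/0.18/0.25/0.45 across
zone 1/2/3/beyond) is bottom-heavy: the proximal zone — which houses the
readily releasable pool — holds few vesicles, while most of the pool sits
beyond 120 nm, as in real presynaptic sections. The hard-core constraint
also caps how many vesicles the narrow proximal band can hold; the uniform
mix is geometrically infeasible at realistic vesicle counts.

## Puncta colocalization and PLA density

`dog_enhance()` band-passes each channel with a DoG adapted to the punctum
size: σ = diameter/(2√(2 ln 2)) (so the requested diameter is the FWHM) and
surround 1.6 σ, the standard band-pass ratio. `make_masks_and_count()`
thresholds each channel at a constant (kept fixed across replicates),
removes components below 4 px, counts particles per channel, and calls a
reference-channel particle colocalized when its component overlaps at least
one pixel of the other channel's mask. Percent colocalization is
100 · dual / n~reference~; the reference channel is an explicit argument
because the convention is asymmetric (swapping the reference changes the
denominator, never the dual count). PLA density is
(100 · dots / field area) / nuclei, i.e. dots per 100 µm² per DAPI⁺
nucleus.

## Paired-pulse electrophysiology

Simulated sweeps are sums of two inward biexponential EPSCs (rise 1 ms,
decay 10 ms) at the stimulus times, with Gaussian current noise; the
protocol's interstimulus intervals (ISIs) are 25–500 ms.
`measure_amplitude()` measures each response as |extremum − baseline| in a
post-stimulus window; the second response's baseline is taken immediately
before the second stimulus, which compensates the residual decay of the
first response at short ISIs (a full exponential decay-subtraction mode is
available via `subtract_decay = TRUE`). `compute_ppr()` measures all
(typically 20) sweeps individually and averages the per-sweep A2/A1 ratios
(mean of ratios — "individually measured and then averaged"); the ratio of
mean amplitudes is also reported, and the two agree in the noise-free
limit. PPR is invariant to scaling and offsetting the trace.

`qc_filter()` implements the rejection rule: the experiment (the whole
cell) is discarded when input or series resistance varies by strictly more
than 20 % of its first-sweep value across the train; exactly 20 % is
accepted (strict inequality — a documented boundary decision).

One numerical note: at the 10 kHz sampling rate, the discrete grid misses
the analytic peak of the biexponential by ~10⁻⁴ relative, so measured
amplitudes are sampling-limited at that precision; the *ratio* is exact to
10⁻⁶ because both responses are sampled at the same phase whenever the ISI
is a multiple of the sampling period (all protocol ISIs are).

## Statistical decision workflow

`stats_workflow()` applies, per dataset: ROUT outlier removal at Q = 1 %
per group, a Shapiro–Wilk normality gate at α = 0.05 (parametric only if
*every* group passes), then the design-appropriate test — t-test or
Mann-Whitney for two groups; one-way ANOVA + Tukey or Kruskal–Wallis +
Dunn for more; two-way ANOVA with Tukey (more than two groups) or Sidak
(two groups) post hocs for interdependent designs. Stars follow \*p<0.05,
\*\*p<0.01, \*\*\*p<0.001, \*\*\*\*p<0.0001.

ROUT is specified for nonlinear regression; group columns are its
degenerate constant-location case, which is how it is applied here: a
robust location by IRLS with Lorentzian weights 1/(1+(r/RSDR)²), scale
(RSDR) from the 68.27th percentile of absolute residuals inflated by
n/(n−1), residuals converted to t-like scores with n−1 degrees of freedom,
and a Benjamini–Hochberg step-up at rate Q on the two-sided tail
probabilities. The construction is validated by its operating
characteristics — location/scale equivariance, ≲1 % false flags on clean
Gaussian data, certain detection of a 10 σ contaminant — rather than by
matching any commercial implementation point for point. Dunn's post hoc
uses rank-based z statistics with the tie correction and a Bonferroni-type
adjustment (the "multiple comparison" flavour); it is checked against a
hand-computed example. Under the null the full workflow's rejection rate at
α = 0.05 is within Monte-Carlo error of 0.05 over 2000 simulations, and
slightly conservative after outlier removal — which is expected, since ROUT
occasionally trims genuine tails.

## What the simulations do and do not show

The simulators reproduce the *structure* of each readout — kinematics,
event shapes, geometries, sweep shapes, noise statistics — under controlled
truth, so they can certify that the measurement code recovers what it
claims to measure. They do not emulate optics beyond a Gaussian PSF, camera
gain, photobleaching, axon curvature (axons are simulated straight; curved
paths are exercised only through the kymograph-extraction interface),
pH-quenching kinetics, endocytosis, stimulus artifacts, or biological
variability between cultures. Passing recovery tests therefore shows the
estimators are correct and well-calibrated at realistic SNR and density; it
does not certify performance on pathological recordings.

Problem sizes used by the test suite were chosen to exercise the study's
own scales: 20 seeded transport movies of 30 vesicles × 300 frames, 100 EM
geometries (10⁶ Monte-Carlo samples for areas), 10 pHluorin fields, 2000
null simulations for the statistics workflow.

## Known limitations

* Tracking identity errors concentrate in multi-vesicle pile-ups; vesicles
  whose anterograde and retrograde excursions nearly balance are
  intrinsically fragile to classify from partial trajectories.
* Zone areas inherit Clipper's arc approximation around polyline ends
  (tolerance 0.05 nm by default; well inside the 1 % Monte-Carlo check).
* The exocytosis baseline assumes events are sparse relative to the 5 s
  median window; sustained activity would bias the baseline upward.
* `normalize_amplitude()` requires matched pre/post ROIs; unmatched or
  zero-baseline synapses propagate as missing values by design.
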