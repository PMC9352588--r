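---
title: "Quantifying biological-motion shoaling and its neural correlates with ShoalVision"
author: "ShoalVision maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biological-motion shoaling and its neural correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ShoalVision)
```

## Scope and data model

Juvenile zebrafish shoal with conspecifics — and with projected black
dots — when the stimulus moves with fish-like kinetics: discrete swim
bouts at roughly 1.25 Hz and an average speed of about 5 mm/s. The same
dot moving continuously at the same average speed is only weakly
attractive. ShoalVision packages the quantitative machinery around this
phenomenon: generating the virtual-conspecific stimuli, scoring the
behaviour they evoke, scoring the tuning of imaged neurons to them,
mapping classified neurons in reference-brain space, and quantifying
condition-dependent immediate-early-gene induction.

The central containers are S4 classes: `Track` (a uniformly sampled 2-D
trajectory in dish millimetres), `StimulusSpec` (a parametric stimulus
description), `TraceSet` (a `SummarizedExperiment` of ROI × time raw
fluorescence with its acquisition rate), `ResponseTable` (ROI ×
stimulus mean dF/F), `NeighborMap`, `DensityField`, `VolumePair` and
`EffectMatrix`. All user-facing units are fixed: millimetres and
seconds for behaviour, micrometres for anatomy, radians for headings.

## Stimulus kinematics

A dot on a circular path of radius $r$ (default 18 mm, the fish's head
at the centre) moving at average speed $v$ subtends
$2\,\mathrm{atan}(d/2r)$ degrees for diameter $d$ and sweeps
$(v/r)\cdot 180/\pi$ deg/s; accelerations convert the same way on the
arc. These conversions are exact algebra and the package reproduces
every printed pairing of linear and angular values (4 mm → 12.7 deg,
5 mm/s → 15.9 deg/s, 12 m/s² → 38.2 × 10³ deg/s², and so on). Bout-like
motion advances the dot by $v/f$ once per bout period ($1/f$, floored
to integer milliseconds: 666 ms at 1.5 Hz); because the jump happens
within a single display frame, the implied acceleration is
$d_{\mathrm{jump}}/\Delta t^2$ with $\Delta t$ the frame interval,
which reproduces all five printed speed/acceleration pairs at a 60 Hz
display.

The Gaussian bout profile morphs between these regimes at a fixed
average speed: one speed pulse per bout period, width chosen so the
profile's maximum absolute slope equals the requested peak
acceleration, amplitude normalized so the mean speed over the period is
exact. The pulses are *periodically wrapped* — the tails of neighbouring
bouts overlap and sum — rather than truncated, because the lowest
tested peak acceleration (0.02 m/s² at 1.5 Hz) requires a pulse wider
than one sixth of the period; wrapping makes the profile degenerate
smoothly to constant speed as the acceleration goes to zero, which is
the physically sensible limit. The pulse width is solved by bisection
on a dense grid; when the requested acceleration would need a pulse
narrower than one display frame it is clipped to one frame with a
warning, since the display cannot render it.

The trefoil path uses the planar parameterization
$(x, y) = s\,(\sin t + 2\sin 2t,\; \cos t - 2\cos 2t)/3$, a smooth,
closed, three-lobed curve whose extreme radius equals the scale $s$.
The exact curve used on published rigs is not standardized; any smooth
closed three-lobed curve serves the same role, and this one has a
strictly positive speed parameterization, so arc-length
reparameterization is well conditioned. Continuous traversal advances
equal arc per frame; bout-like traversal steps so that each jump's
straight-line displacement is exactly $v/f$, the quantity a bout
actually displaces.

Naturalistic trajectory replay smooths recorded tracks with a unit-sum
Hamming window (length 20, valid mode), exactly the convolution
`stats::convolve(x, rev(w), type = "filter")`; looming discs ramp the
subtended angle linearly between the configured start and end sizes
(0.6 deg to 110 deg in 83 ms on the imaging rig, 500 ms in the
behavioural assay). Whole-field Fourier-pattern synthesis is out of
scope: its published description does not determine band edges or phase
handling, so only the moving-dot stimuli are generated.

## Shoaling statistics

Attraction uses a time-shift null. The real mean inter-animal (or
animal–dot) distance is computed in non-overlapping 5 min chunks
(IADr); within each chunk the partner trajectory is cyclically
time-shifted and the mean distance recomputed (IADs), and attraction is
$(\mathrm{IADs} - \mathrm{IADr})/\mathrm{IADs}$, averaged over chunks
per animal. The shift magnitudes are not standardized anywhere; the
package uses ten shifts at $k \cdot \mathrm{chunk}/11$, $k = 1..10$,
which spaces them symmetrically and keeps the smallest shift near 27 s,
long compared with bout time scales. Shifting destroys the temporal
correlation between the animals while preserving each animal's spatial
occupancy, so shared place preferences (dish walls, corners) do not
masquerade as attraction.

Neighbour-density maps histogram the partner's position in the focal
animal's egocentric frame (focal at the centre, heading up) over a
60 mm × 60 mm map. The bin size (1 mm) is chosen to resolve the 3 mm
smoothing kernel applied afterwards. When no heading channel is
recorded it is derived from frame-to-frame displacement; frames with
less than 0.1 mm displacement are skipped because a resting fish has no
defined heading. Egocentric coordinates are snapped at 1 nm before
binning so that samples lying exactly on a bin boundary (a partner dead
ahead) bin deterministically.

The repulsion score quantifies the central density deficit: the map is
Gaussian-smoothed (σ = 3 mm), 24 radial line scans of 5 mm width
(realized as five parallel rays, bilinear interpolation) are averaged
from the centre to 29 mm, and the score is the area between the scan's
peak level and the scan at radii left of the peak, divided by the full
29 mm scan length. This "area above the scan, left of the peak" reading
is stated explicitly because the verbal definition admits
alternatives; it is zero exactly when density is maximal at the centre,
and grows with both the depth and the width of the central void.
Attraction and repulsion are deliberately separable: a strongly coupled
follower that keeps a minimum distance scores high on both, which is
the behavioural dissociation the ablation experiments rest on.

Bout detection thresholds the frame-to-frame speed at median + 3 MAD —
a noise-adaptive rule, since no fixed threshold is published — and
reports contiguous supra-threshold spans as bouts. Looming escapes
follow the displacement rule: a trial is an escape when the path length
in the 1 s after loom onset exceeds twice the path length in the 1.3 s
before; trials with truncated windows are excluded rather than padded.

## Neural tuning

dF/F is computed per stimulus presentation against the mean
fluorescence in the 5 s before onset. Baselines below 1% of the ROI's
median fluorescence flag the ROI-presentation invalid instead of
producing unbounded ratios. Responses are averaged across presentations
of the same stimulus first, then over the full 22.6 s stimulus window,
yielding one value per ROI and stimulus.

The responsiveness filter is relative: for each stimulus, the given
percentile (95 by default; 90 and 50 variants for sparser recordings)
of that stimulus's responses across ROIs sets a cutoff, and ROIs
strictly above the cutoff for at least one stimulus are retained.
Percentile 0 disables the filter. The reference distribution
(per-stimulus, across ROIs) is a documented choice — the published
description does not pin it down — and is configurable.

The bout preference index splits stimuli by bout frequency into
bout-like (0.75–3 Hz) and continuous (6–60 Hz) categories regardless of
size or direction and computes

$$\mathrm{BPI} = \frac{\overline{R}_\mathrm{bout} -
\overline{R}_\mathrm{cont}}{\overline{R}_\mathrm{bout} +
\overline{R}_\mathrm{cont}},$$

with BPI > 0.5 (a threefold higher bout response) defining bout
preference neurons. Negative mean responses are admitted — the index
may then leave [−1, 1] and is flagged rather than silently clamped —
and an exactly zero denominator yields NA with a reason code.

Tuning peaks interpolate the per-stimulus responses with a degree-2
interpolating B-spline (triple boundary knots, interior knots at
support midpoints; the scheme reproduces quadratics exactly) and return
the argmax over the support interval. Frequency tuning runs on a log2
axis: the supports span 0.75–60 Hz, and on a linear axis the 60 Hz
point dominates the geometry and degrades the peak estimate.

## Anatomical density and c-fos quantification

Cell-coordinate density uses an isotropic Gaussian KDE (bandwidth 10 µm
for juveniles, 14 µm for 7 d.p.f. larvae), fitted separately per
hemisphere (midline split; points exactly on the midline count as
left, a deterministic tie-break) and evaluated on each hemisphere's own
voxels so a hemisphere without cells stays exactly zero. The merged
field is masked to the brain and then rescaled so the masked density
integrates to the cell count — masking before normalization, so no mass
is attributed to voxels outside the brain. The evaluation grid (2 µm
default) is a resolution choice only; densities are reported per
1000 µm³ regardless. Contours binarize the field at the stated
densities (0.1, 0.15, 0.3 cells per 1000 µm³), take a
maximum-intensity projection along an anatomical axis and trace the
binary boundary by marching squares. Region fractions assign each cell
to its nearest voxel's label, with an explicit `unassigned` catch-all
so fractions always sum to one.

c-fos quantification divides the activity channel voxel-wise by the
reference (elavl3) channel, cancelling the shared depth attenuation;
voxels whose reference falls below 1% of the in-brain median are masked
out rather than divided. Quantification uses the unfiltered reference —
the 3-D Gaussian option exists for display only. Bulk cluster signal is
the mean normalized intensity over each cluster mask; effects per
condition are Cohen's *d* against the no-stimulus baseline
(difference of means over the pooled SD; negative *d* = below
baseline) with two-tailed Student *t*-tests — equal-variance by
default, matching the generic published description, with a Welch
switch — and significance tiers Bonferroni-corrected within each
cluster's family of stimulus-vs-baseline comparisons (α/3 for the
standard three conditions). Effect profiles are clustered with average
linkage on Euclidean distances; rows with undefined *d* are dropped
with a report, never imputed.

## The synthetic-data module

Every pipeline stage has a generator that produces its inputs with
known ground truth, closing the testing loop without animal data.

**Dyads** (`genDyad`) are bout-structured swimmers in a 100 mm dish:
Poisson-timed bouts at 1.25 Hz displacing `speed/freq` (5 mm/s average)
along a heading that random-walks per bout, with reflective walls. A
follower biases its heading towards the partner beyond the preferred
distance (weight growing with the attraction gain and the range error)
and away inside the exclusion radius. This is a test harness with the
right phenomenology — attraction monotone in gain, a central
neighbour-map void matching the exclusion radius — not a behavioural
model; it makes no claim about real interaction rules.

**Calcium traces** (`genTraces`) mix three phenotypes: frequency-tuned
neurons (13% by default, the fraction of bout-preferring neurons the
juvenile recordings report), untuned equal responders (37%) and silent
neurons (50%). Tuned neurons carry log-Gaussian frequency tuning with
per-neuron centres spread 0.35 log2 units around 1.2 Hz: real
populations show a spread of tuning peaks, and 0.35 is the widest
spread for which every tuned neuron's bout:continuous response ratio
stays above 3, keeping the ground-truth class aligned with the BPI > 0.5
rule. Responses are filtered through a single-exponential calcium
kernel (τ = 7 s, instantaneous rise — rise kinetics are irrelevant to
22.6 s window means), sampled at 5 volumes/s with Gaussian noise and
mean-downsampled fivefold, mirroring the nuclear GCaMP6s acquisition.
The recovery property tests use the 90th-percentile responsiveness
variant: a relative filter retains at most (100−p)% of ROIs per
stimulus, so the 95th-percentile variant cannot by construction retain
a 13% selective class in a three-phenotype population, while at the
90th percentile the silent class is excluded and the tuned class
retained in full.

**Cell points** (`genCellPoints`) are Gaussian clusters at stated
centres; **two-channel volumes** (`genCfosVolumes`) build the reference
as a depth-attenuated base intensity (`exp(-z/λ)`) and the activity as
the reference scaled inside each cluster by an animal-level factor
drawn so the condition group differs from baseline by the planted
Cohen's *d* given the between-animal SD. All generators are
bit-reproducible under a seed.

What the generators do *not* emulate — real swim kinematics beyond bout
statistics, GCaMP photophysics, registration error, segmentation
artefacts — bounds what passing tests show: they demonstrate that the
analysis code recovers planted structure under the stated noise, not
that the analyses are robust to every failure mode of real recordings.

## Numerical choices and problem sizes

Chunked statistics drop trailing partial chunks; ties in argmax
operations resolve to the first (smallest-radius, lowest-index)
candidate; the repulsion scan samples at 0.25 mm with bilinear
interpolation; KDE normalization tolerates |mass − N| < 10⁻⁶N; the
spline argmax refines a 2001-point grid search with golden-section
optimization. The test suite simulates 100 min of independent-dyad
swimming (20 attraction chunks), 30 min followers, 1000-neuron
populations and 12 × 10 × 8-voxel volume sets at n = 8 animals per
group — sizes chosen so the full suite runs in well under half an hour
on one core while keeping Monte-Carlo tolerances meaningful.

## File formats

Tracks and schedules are CSV with fixed headers and units; trace
matrices are delimited text with a JSON sidecar carrying the rate and
coordinates; volumes are NRRD (raw encoding, double precision,
lossless — implemented in-package as no installed R package reads NRRD)
or 32-bit TIFF stacks with a scale/offset sidecar (quantized to ~2×10⁻¹⁰
of the intensity range by the format). `runPipeline()` drives the four
analyses from a JSON configuration whose defaults are the study's
standard parameters, rejects unknown keys, and emits a resolved-config
report with the package version and seed; reruns under the same seed
are byte-identical.

## Known limitations

The rostrocaudal phrase in the published KDE description is read as a
hemisphere-wise (left/right) split; attraction averages chunk scores
per animal rather than pooling frames; the whole-field pattern
generator is deliberately absent; and the behaviour generator's
follower rule is the simplest model with the required phenomenology,
not a fitted one. Registration, segmentation and template construction
are upstream of this package and consumed as inputs.
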