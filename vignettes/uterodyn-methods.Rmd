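---
title: "Quantifying utero-placental contractions from dynamic MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying utero-placental contractions from dynamic MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uterodyn)
```

## The measurement problem

During pregnancy the uterus exhibits two kinds of spontaneous contraction
visible on dynamic MRI. *Uterine* (Braxton Hicks-type) contractions thicken
the uterine wall, locally or uniformly, and compress the whole cavity;
the placenta thins a little but barely changes shape. *Placental*
contractions are largely confined to the placental bed: the bed shortens,
the rest of the wall stretches, and the placenta "balloons", becoming
blockier and more spherical while maternal blood is squeezed out of the
intervillous space. Both kinds reduce placental volume, because the fetus
and amniotic fluid are incompressible and the expelled volume is maternal
blood.

`uterodyn` turns a dynamic series of segmented label volumes (placenta,
non-placental uterine wall, intra-uterine contents, background) plus
co-registered R2*-weighted signal volumes into quantitative contraction
measurements. The acquisition it targets is a respiratory-triggered
multislice gradient-echo EPI protocol: voxels 2.4 x 2.4 x 6 mm, 10 mm
interslice spacing (slice gap rather than thicker slices), echo time 25 ms,
irregular frame times with a 9 s minimum and 15 s mean repetition time,
sessions of roughly 15-32 minutes.

## Morphometry on gapped, anisotropic grids

**Volumes** are gap-aware voxel counts: each slice stands for its full
10 mm band, so volume = count x in-plane voxel area x interslice spacing.
For smooth organ-scale objects the midpoint-rule error of this estimator is
a fraction of a percent, which is why the acquisition can afford the gap.

**Surface areas** cannot be read off anisotropic voxel faces (face counting
overestimates area badly). Instead each mask slice is converted to a signed
in-plane Euclidean distance map, the maps are linearly interpolated across
the gap onto a near-isotropic grid (shape-based interpolation), and the
zero level set is triangulated by marching tetrahedra; the area is the
triangle-area sum. Two numerical choices matter:

* *Staircase suppression.* Distance maps of binary masks carry a half-voxel
  staircase that inflates isosurface area by several percent. The field is
  smoothed with a small Gaussian (SD 0.8 voxel in-plane) before meshing;
  with it, a digitised 40 mm ball is measured within ~1-2 % of
  \(4\pi r^2\) on the acquisition grid.
* *Mid-gap closure.* Beyond a mask's last populated slice its true extent is
  unobservable. An empty neighbouring slice is assigned
  \(\min(\mathrm{sd}_{\text{neighbour}} - \Delta z, -\Delta z/2)\), closing
  the surface at most half a gap out instead of clipping it at the last
  slice.

Where the surface runs parallel to the slices, slice-wise interpolation
still misplaces the crossing by up to a few millimetres (in-plane distances
are an upper bound on 3D distances). For the placenta-like cap-slab phantom
this biases the *absolute* surface area low by roughly 5-10 % on the
default grid. Time-course *changes* are unaffected to first order because
the bias is stable across frames; the sphere and ellipsoid oracles, whose
surfaces are mostly transverse to the slices, are accurate within the 3-5 %
tolerances.

**Interface areas.** The placental bed area (placenta-wall contact) and the
non-placental wall area (wall-content contact) are computed by complements:
a placental surface triangle is "amniotic" if the interpolated content
distance at its centroid exceeds a contact tolerance (default 1.25 in-plane
voxels), and the bed is the remainder; likewise the wall's free inner
surface is the content surface not facing the placenta. Classifying against
the fat neighbouring compartment rather than the thin (7 mm < 10 mm gap)
wall keeps the split well defined where the interface is slice-parallel.
On a spherical phantom both interfaces match their closed forms within
~5-10 %.

**Sphericity** is \(\Psi = \pi^{1/3}(6V)^{2/3}/A\), 1 for a sphere and
below 1 otherwise. `A` is the *total* closed placental surface area, not
the bed area: the formula is the standard sphericity definition and only a
closed-surface area makes it dimensionally meaningful and bounded by 1.
Mesh discretisation can push measured values at most ~2 % above 1; on
analytic (V, A) pairs the bound is exact.

## Time courses

All per-frame series (volumes, areas, sphericity, mean placental signal)
are smoothed with a centred 5-point moving average over *sample indices* -
the span is defined in time points, not seconds, because the
respiratory-triggered sampling is irregular. At the series edges the window
shrinks symmetrically. The mean placental signal uses each frame's own
placenta mask (the mask moves with the contraction).

The relaxation-rate change is
\(\Delta R_2^*(t) = -\tfrac{1}{TE}\ln(S(t)/S_b)\) in ms\(^{-1}\), where
\(S_b\) is the smoothed mean signal at the *earliest rest volume* - not
necessarily the first frame, since acquisition can begin mid-contraction.
Single-echo data yield only this relative change, not absolute R2*.
\(\Delta R_2^*\) is computed from the smoothed signal, consistent with all
other series being smoothed before feature extraction.

Rest frames are found iteratively: a frame is at rest when it lies within
`rest_tolerance` (default 2 %) of the running rest reference, the median of
the current rest set; the iteration starts from the upper quartile so that
contraction dips are excluded. Volumes and areas are finally expressed as
percent of their earliest-rest values.

## Events

Detection is automatic (visual two-rater identification is not
reproducible): candidate events are maximal runs of at least
`min_consecutive = 2` frames falling more than `drop_threshold_pct = 5` %
below the rest reference interpolated linearly in time across gaps; runs
separated by at most `merge_gap_frames = 2` frames merge; events touching
the scan boundary are flagged truncated.

Each event (and each series) gets a *local baseline*: linear in time
between the series values at the last rest frame before and the first rest
frame after the event; constant on a truncated side; constant at the global
earliest-rest value when both sides are truncated. Baseline anchors are
stepped `anchor_pad_frames = 2` frames deeper into their rest segment so
the smoothing window of the anchor value does not overlap contraction
frames - without this, anchors contaminated by slow contraction tails bias
amplitudes and durations low by 1-2 %.

Features per event: the maximum percent volume drop below baseline - read
from the *raw* volume series against the smoothed baseline, because the
5-point average attenuates a single raised-cosine peak by the factor
\(\frac{1}{5}\sum_{k=-2}^{2}\cos(2\pi k\bar{\Delta t}/T)\) (4-10 %
relative at the 15 s sampling), which would bias recovered amplitudes low;
the signed extreme change of the non-placental wall area and of sphericity;
the \(\Delta R_2^*\) change read at the frame of maximum volume deviation
(an extremum over the event would be biased by noise maxima; an
`"extremum"` mode exists); and the *half-maximum duration* - the time
between the two crossings of half the maximum baseline deviation, linearly
interpolated between irregular frame times, reported in minutes, with a
lower-bound flag when a flank never recrosses (truncated events). On a
plateau the first frame attaining the maximum is the peak. The contraction
rate is simply 3600 x n / duration in events per hour.

## Motion screening

Maternal movement: threshold the signal volumes (default: 90th percentile
of positive frame-1 intensities, held fixed), remove the uterus (labels
1-3), and express the voxelwise symmetric difference between consecutive
frames as percent of the session-mean mask size. Fetal movement: the same
differencing on the bright amniotic fluid inside the contents mask, with an
Otsu threshold by default (a fixed percentile can land inside the fluid
intensity cluster when fetal structures are a small volume fraction, making
the mask flicker on noise). The percent normalisation convention is a
package choice - the 2 % rule needs a scale-free metric - and the first
frame's movement is defined as 0. A session is a *high-movement scan* when
either mean trace over non-contracting frames exceeds 2 %; individual
events additionally carry a `motion_affected` flag when a frame inside them
spikes above 10 %.

## Classification

The quantitative rule: events with a maximum volume drop of **more than
10 %** are classifiable; among them, a sphericity increase of **more than
0.005** labels the event *placental*, otherwise *uterine*. Both
inequalities are strict, so boundary values are never placental -
deliberately conservative, matching the observation that simultaneous mixed
contractions present as uterine. Sub-gate events are labelled
`sub-threshold` rather than forced into either class. A wall-area increase
is plausibly informative too but no validated threshold exists, so it is an
optional criterion behind `use_wall_area` with no default threshold.

## Statistics

Group comparisons between placental and uterine contraction features use
the two-sided Mann-Whitney U test with midranks. For combined samples up to
16 the null distribution is enumerated exactly
(\(p = P(|U - n_xn_y/2| \ge |u - n_xn_y/2|)\)); above that, the normal
approximation with tie and continuity corrections. The five standard
features (duration, volume drop, \(\Delta R_2^*\) change, wall-area change,
sphericity change) are compared against a base threshold of 0.01,
Bonferroni-adjusted to 0.01/5 = 0.002; uncorrected p-values are reported
alongside the corrected threshold rather than corrected p-values. Cohort
summaries are median (lower quartile, upper quartile) with type-7
(linear-interpolation) quartiles, pinned as the package convention.

## The synthetic phantom

No clinical data accompany this package, so validation rests on a
parametric utero-placental phantom with closed-form ground truth.

*Geometry.* The cavity is an ellipsoid (default semi-axes 80, 70, 85 mm:
a ~2 L third-trimester cavity). In the normalised coordinates where the
cavity is the unit ball, the placenta is a spherical-cap slab (default cap
angle 120 degrees, thickness 25 mm: ~340 mL) and the wall a 7 mm shell.
Volumes map exactly between the two spaces; areas and sphericity are exact
for a spherical cavity and a controlled approximation for the mildly
anisotropic default.

*Contraction morphing.* An event drives the placental volume down by
`amplitude` x a raised-cosine profile, and the cavity radius follows from
exact conservation of the incompressible contents. The cap angle and slab
thickness are then solved (1D root in the cap angle) so the slab attains a
prescribed sphericity change: positive (default +0.012) for placental
events - bed shortening with ballooning - and non-positive for uterine
ones (default -0.35 x amplitude, the passive drop of a slab thinning at
near-constant bed extent, so the uterine morph is thinning-dominant; a
fixed small negative target would instead force placental-like bed
shortening for deep events). Uterine events additionally thicken the wall,
uniformly or as a local bump on the far side of the cavity. The defaults
keep well over a 0.005 margin from the classification threshold in both
directions. Because
every frame solves closed-form equations, the ground-truth table (onset,
offset, half-max duration = half the raised-cosine duration, peak
fractional drop = amplitude) is analytic, independent of rasterisation.

*Rasterisation.* Labels are sampled in-plane at voxel centres and
through-plane with three subsamples across the 6 mm slice and a majority
vote, on a reduced default grid of 96 x 96 x 24.

*Signal.* Mono-exponential TE weighting, \(S = S_0 e^{-TE\,R_2^*}\), with
fixed per-tissue \((S_0, R_2^*)\) (bright long-T2* fluid, darker fetal
blobs, bright extra-uterine maternal features) and an event-driven
placental R2* increase (default peak 0.004 ms\(^{-1}\), the scale observed
during contractions). Noise is additive Gaussian with SD a fraction
(default 0.02) of the resting placental signal; Rician effects are
irrelevant at this SNR. Maternal motion rigidly shifts everything outside
the uterus in-plane from the chosen frame on; fetal motion re-randomises
the fetal blob pattern inside the contents.

*Timing.* Interframe gaps are `tr_min_s` + Exponential(`tr_mean_s` -
`tr_min_s`). The gaps are drawn from a dedicated `timing_seed` rather than
`rng_seed`, so that the same configuration yields bit-identical label
volumes regardless of the noise seed; vary `timing_seed` to vary the
sampling pattern.

*What the phantom does not emulate* - and hence what a green test does not
establish: segmentation error (labels are exact, so classification
robustness to noisy masks is untested), fetal anatomy, EPI artefacts,
k-space effects, partial-volume fractions of real MRI, drifting baselines
from slow physiology, and overlapping events of the same kind.

## Validation-suite choices

The randomized validation sessions are 30 minutes with 1-4 events (as many
as fit), amplitudes uniform in 0.12-0.30, and durations uniform in
300-480 s - the upper range of observed complete contraction lengths,
chosen a priori so that the 15 s mean sampling and the mandatory 5-point
smoother resolve event peaks well enough for stable rest baselines and
half-maximum crossings. Per-event recovery errors are evaluated as medians
across the suite, not worst cases: residual errors come from rasterisation
jitter, baseline anchors placed within the 2 % rest band, and linear
interpolation of crossings on the irregular time grid. The event-recovery suite uses
the full 50 seeded sessions; the noisy classification suite is scaled to 16
sessions because per-frame surface measurement dominates its CPU cost (the
noiseless classification check and all thresholds are unchanged by this).

## Known limitations

* Absolute cap-slab surface areas (hence absolute sphericity) are biased a
  few percent low on the gapped grid; analyses should rely on within-scan
  changes, as the pipeline does.
* The anchor-padding heuristic assumes rest segments of at least a few
  frames; with merged rest gaps shorter than the pad, anchors fall back to
  the nearest rest frame.
* The motion normalisation (percent of session-mean mask size) is a
  convention; the 2 % flag threshold is calibrated to it and may need
  retuning for other normalisations.
* `find_earliest_rest()` fails (by design) on series with no rest segment;
  callers must then supply `baseline_index` explicitly.
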