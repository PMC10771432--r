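---
title: "Mapping spinal cord blood flow with cordflow: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping spinal cord blood flow with cordflow: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cordflow)
```

## The problem

After a contusion injury of the spinal cord, blood flow reorganizes along
the rostro-caudal axis: flow collapses at the epicenter (the *umbra*), is
elevated in the immediately flanking tissue (the *penumbras*), and is
unchanged in distal, presumably unaffected cord. cordflow quantifies this
reorganization from mid-sagittal ultrasound recordings acquired through a
laminectomy window, in two arms:

* **Non-contrast arm.** Power-Doppler/SMI-type recordings are decoded into
  a per-pixel *velocity index* (arbitrary units, monotonically related to
  flow velocity but not calibrated to mm/s) and averaged over time.
* **Contrast arm.** After a microbubble bolus, the per-pixel
  time–intensity curve rises to a peak and washes out approximately as a
  first-order exponential. The magnitude of the washout rate constant
  $k$ (1/s) serves as the flow surrogate: faster clearance, greater
  perfusion. $k$ is robust to variation in the injected bolus amount,
  unlike peak intensity.

Both arms end in the same spatial object: the *area-adjusted flow index*
versus signed distance from the injury, from which injury zones are
labeled automatically.

## The contrast pipeline

Each pixel's intensity series is smoothed with a 32-sample simple moving
average (centered, shrinking windows at the edges, so output length equals
input length), and the model

$$y(t) = A\,e^{-k\,(t - t_\mathrm{peak})}$$

is fit to the segment starting at the smoothed maximum. Two rules assign
$k = 0$ to pixels that never received microbubble signal: a maximum
intensity below 0.015 AU, or a peak occurring at or after 75 s into the
recording (boundary inclusive). These rules are exhaustive — every pixel is
either fit or explicitly zeroed, and the map contains no NaN.

**Fitting.** We fit by linear least squares on $\log y$ with weights
$w_i = y_i^2$. The weighting matters: under additive noise the variance of
$\log y$ is approximately $\sigma^2/y^2$, so $y^2$ weights are the standard
linearization of the nonlinear problem. They are exact on a clean
exponential and, at the generator's default noise, reduce the median
relative error of $k$ from tens of percent (unweighted, dominated by the
noise-floor tail) to below 1%. Post-peak samples at or below 0 AU are
excluded (their logarithm is undefined); a nonlinear refinement on the
intensity scale is available behind `refine = TRUE` but is not the default
because the weighted linear fit already attains the same answer on clean
decays at a fraction of the cost. Negative slope estimates are clamped to
$k = 0$. At least 10 usable post-peak samples are required.

**Speckle removal.** Occasional microbubble aggregates produce isolated
bright speckle in the decay map. Following the published processing chain,
the map is opened with a *non-flat* disk structuring element
$b(s) = h\sqrt{1 - |s|^2/r^2}$ ($r = 5$ px, $h = 0.05$ 1/s): grayscale
erosion then dilation. The opening is anti-extensive and idempotent, and
removes structures narrower than the disk while lowering a constant image
not at all. Image borders use symmetric reflection (the choice is
documented here because the operation's source description is silent on
boundary handling; reflection makes the opening equal to opening the
symmetrically extended image, preserving anti-extensivity and idempotence
at the borders).

## The non-contrast pipeline

Scanner color-Doppler output is either already index-valued (grayscale
stacks) or decoded from RGB by nearest-neighbor lookup in a
color-to-velocity-index table. The exact colormap of a clinical scanner is
generally proprietary, so the table is an input; `defaultHotLut()`
provides a documented red-to-white ramp whose colors are far from
grayscale B-mode background. Pixels farther than `maxColorDistance` from
every table color decode to 0. Each 5-s recording is then collapsed by the
per-pixel arithmetic mean (`timeAverageMap`).

## From maps to spatial profiles

The user annotates each recording with an injury line (transverse to the
cord axis) and two border polylines that exclude the anterior and
posterior spinal arteries. Every ROI pixel receives a signed minimum
Euclidean distance to the injury line segment (rostral/left negative),
and pixels are pooled into half-open 0.1 mm bins whose edges are anchored
at 0 mm — anchoring makes "the closest peak on either side of 0" well
defined. Each bin is summarized by the area-adjusted index

$$I = v \cdot \frac{A_{px}}{A_{ROI}},$$

the mean brightness of flowing ("colored") pixels times the fraction of
the bin's area they occupy. A colored pixel is one with value strictly
above a configurable threshold; at the default threshold 0 the index
reduces algebraically to the plain mean including zeros, which also gives
the conservation identity $\sum_b I_b n_b = \sum_{ROI} v$ used as a
self-check. Empty bins are flagged missing, never silently zero.

The binned profile is filtered with a 1 mm averaging window. 1 mm over
0.1 mm bins is ten bins — an even number — so the centered filter uses the
nearest odd count, 11 bins (1.1 mm); this is configurable. Edge bins use
shrinking windows, and missing bins are excluded from each local mean, so
smoothing never extends the profile's support by more than half a window.

## Zone labeling

On the post-injury profile:

1. **Penumbras.** Local maxima with topographic prominence at least
   0.03 AU (prominence = drop to the lowest contour isolating the peak,
   the `findpeaks` convention, implemented explicitly and oracle-tested);
   on each side of 0 mm the qualifying peak closest to the injury is the
   penumbra. A side without one fails labeling (recorded, not an error).
2. **Umbra.** The minimum of the profile strictly between the two
   penumbras. A minimum attained over consecutive tied bins is reported at
   the center of the tie; non-consecutive ties break toward 0 mm (our
   choice; the tie-center rule covers only consecutive bins). A strictly
   monotone segment returns the endpoint minimum with a QC note.
3. **Prominence.** Penumbra flow minus umbra flow, per side.
4. **Extent.** On each side the half-maximum level is the mean of that
   side's penumbra flow and the umbra flow; walking from the umbra toward
   the penumbra, the crossing is located by linear interpolation between
   the bracketing bins (sub-bin extents imply interpolation even where the
   convention is unstated). Extent = caudal crossing − rostral crossing.
5. **Distal flows.** Mean profile strictly beyond each penumbra; an empty
   side is missing, not zero.

Pre-injury parameters are read from the pre-injury profile at the
locations labeled post-injury, so pre/post compare the same tissue; the
half-maximum extent is undefined pre-injury and reported `NA`. Umbra and
penumbras are single points by design (an option for region-based variants
exists in the zone table but single points emphasize flow differences).

## Temporal tracking

Continuous recordings are analyzed frame by frame with identical geometry
and binning; zones are re-detected every frame, the three location traces
are median-filtered, and flows are sampled at the filtered locations
(distal means recomputed per frame beyond the filtered penumbras; a flag
freezes them instead). Per-frame labeling occasionally jumps — tissue
cannot do that — hence the filter.

The filter is specified as "size 40 frames". We implement the order-40
filter with a centered 41-tap window $[i-20, i+20]$, shrinking
symmetrically at the edges so every window has an odd sample count. The
odd tap count is essential, not cosmetic: with an even 40-sample window, a
run of exactly 20 aberrant frames fills half the window and the
even-count median (mean of the middle two order statistics) leaves half
the excursion in place; with 41 taps every run of up to 20 frames is
removed *exactly*, which is the robustness property the filter exists to
provide.

## Cross-modality comparison

Per subject, the two arms' profiles are compared by Spearman rank
correlation over shared non-missing bins (average ranks on ties): the
association between a velocity index and a decay constant is expected to
be monotone, not linear. Across subjects the correlations are averaged
through Fisher's z transform, $\tanh(\mathrm{mean}(\mathrm{atanh}\,\rho))$
— appropriate because contrast-arm profiles vary more between animals than
non-contrast ones. $|\rho| = 1$ diverges on the z scale and is rejected
unless the caller opts into clipping. Both the per-subject p-values and a
transform-domain test of the averaged correlation are emitted, labeled
distinctly. The per-bin discrepancy curve rescales each profile to
$[0, 1]$ by its own maximum before differencing (the two arms carry
different units); the rescaling convention is this package's own.

## The phantom generator

No recordings ship with the package, so every stage is validated against
synthetic scenes with analytic ground truth.

**Scene.** A cord band between two gently undulating borders contains a
horizontal axial vessel (anterior-spinal-artery-like, constant row),
perpendicular sulcal-like branches descending to the ventral border every
0.55 mm, and a dense perforator lattice (checkerboard phase, density 1/2).
True flow at a vessel pixel is an analytic profile of its signed distance
from the injury line: baseline 0.5 AU, a Gaussian dip at the epicenter
(depth 0.45 AU, sd 0.4 mm), and Gaussian penumbral bumps at ±2.0 mm
(height 0.2 AU, sd 0.4 mm). Default scenes are 96×224 px at 0.05 mm/px.

Three geometric choices make sub-bin validation honest rather than lucky,
and are worth recording. First, the perforator field is a regular lattice,
not Bernoulli noise: at the 0.1 mm analysis scale the in vivo capillary
bed is effectively dense and uniform (thousands of pixels per bin),
whereas a sparse random field's per-bin density ripple is large enough to
move the filtered profile's flat penumbra peak by more than a bin —
a phantom artifact, not a pipeline error. Second, the injury line sits at
a half-pixel column, as a human annotation effectively does; a line placed
exactly on a pixel-center column makes every bin's pixel distances pile on
one side of the bin center and biases the whole profile outward by half a
pixel. Third, the dip and the penumbral bumps are separated by more than
half the 1 mm filter width: when a dip tail reaches into the filter window
at the peak, filtering itself displaces the smoothed maximum outward
(~0.06 mm for ±1.5 mm offsets) — a real property of the published
filtering, which a phantom meant to test *labeling* should not conflate
with labeling error. `truthZoneLocations()` computes the truth's actual
extrema numerically and is the reference for all recovery tests.

**Non-contrast render.** Per-frame value = true flow × cardiac modulation
(raised 5 Hz sinusoid, mean 1 — rat-like; only its mean matters to
time-averaged maps), degraded by Doppler dropout (pixel-frame zeros,
default probability 0.15) and additive Gaussian noise (sd 0.05 AU, clipped
at 0) on vessel pixels. Off-vessel pixels are exactly 0. No noise
statistics are published for SMI dropout; these defaults are stated, not
calibrated.

**Contrast render.** Microbubbles fill the capillary bed, so the perfused
field is the local disk-mean (radius 2 px) of vessel flow over the band —
a spatially dense field, which is what makes the radius-5 opening benign
on real decay maps. Each perfused pixel ramps linearly to a 0.5 AU peak
(arrival 8 s, rise 7 s; the rise shape is inert because only the post-peak
segment is fit) and washes out with $k = 0.2\,(\text{1/s per AU}) \times$
local flow, placing $k$ on the 0.05–0.15 1/s scale implied by the 0.05 1/s
structuring-element height of the published post-processing. Additive
noise (sd 0.002 AU) is truncated at ±5 sd so unperfused background stays
strictly below the 0.015 AU threshold. Optional speckle injects isolated
≤2 px blobs with artificially fast washout to exercise the opening. The
per-pixel true $k$ field is stored in the stack metadata as the oracle.
The exponential carries no additive offset (pure first-order decay, as
the model is stated).

**Tube phantom.** The benchtop validation is emulated as a straight tube
(408 or 506 µm bore) whose rendered index is a strictly increasing
saturating function of the known velocity, $v/(v + 30\,\text{mm/s})$, with
the SMI noise model; the area-adjusted index over the tube recovers the
velocity ranking (Spearman ρ = 1 noiseless; ≥ 0.95 with the default noise,
mirroring the max-scale benchtop result). Tube diameter enters only
through geometry, so two bores at one velocity give the same expected
index.

**What passing these tests shows — and does not.** The phantom
demonstrates that the *pipeline* recovers known kinetics, geometry and
zone structure at and below the published noise scales. It does not
emulate acoustic physics: no speckle statistics, beam geometry,
attenuation, out-of-plane flow, motion, or scanner compression. Agreement
on phantoms is necessary, not sufficient, for in vivo validity.

## Problem sizes and runtime choices

Validation uses 96×224 px scenes, 195-frame (5 s at 39 fps) non-contrast
stacks, and 150 s contrast renders at 4 fps (decay fitting uses the time
axis, so the map is insensitive to frame rate; the per-pixel recovery
check runs at 10–39 fps where the 32-sample window is short relative to
the bolus rise, since at very low rates the smoothing transient at the
peak dominates the small residual bias of the fit). Decay recovery is
checked on 500 pixels over $k \in [0.01, 0.2]$ 1/s at 39 fps/150 s; zone
recovery on 50 seeded scenes per noise level. These sizes are the
package's validation conditions; all are configurable.

## Known limitations

* Velocity index is not velocity; absolute flow in mm/s is out of reach
  for this method, and Doppler angle correction is not attempted.
* The color decode depends on a user-supplied LUT; a wrong LUT degrades
  the non-contrast arm silently (monotonically wrong maps can still
  correlate).
* Zone labeling assumes one dip flanked by two prominent peaks; diffuse
  or multi-focal injuries violate the model and surface as labeling
  failures or mislabels — the published workflow verified labels visually,
  and `ZoneLabels` carries QC notes for the same reason.
* The umbra tie rules make the labeled epicenter disagree with the manual
  injury mark by design when the flow minimum is displaced.
* Axial-plane profiles, destruction-replenishment and SVD-based contrast
  quantification are out of scope.
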