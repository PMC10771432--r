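# cordflow

Spinal cord blood flow mapping from non-contrast and contrast-enhanced
ultrasound.

After a contusion spinal cord injury, blood flow collapses at the
epicenter (the **umbra**), rises in the flanking tissue (the
**penumbras**), and stays unchanged distally. `cordflow` turns
mid-sagittal ultrasound recordings of the injured cord into quantitative
maps of this reorganization, through two independent arms that meet in a
common spatial representation:

* **Non-contrast (SMI/power-Doppler) arm** — RGB or grayscale recordings
  are decoded to a per-pixel *velocity index* (AU) and averaged over time.
* **Contrast-harmonic arm** — after a microbubble bolus, each pixel's
  time–intensity curve is smoothed (32-sample moving average) and fit,
  from its peak, to a first-order washout `y(t) = A exp(−k (t − t_peak))`.
  The decay constant `k` (1/s) is the flow surrogate; pixels whose peak
  stays below 0.015 AU or occurs ≥ 75 s into the recording are assigned
  0 1/s, and the map is cleaned with a non-flat ("offset disk") grayscale
  opening (radius 5 px, height 0.05 1/s).

Both maps are binned by signed distance to a user-drawn injury line into
0.1 mm bins of the **area-adjusted index** `I = v · A_px / A_ROI` (mean
brightness of flowing pixels × their area fraction), filtered with a 1 mm
averaging window, and the resulting profile is labeled automatically:
penumbras (nearest peaks of topographic prominence ≥ 0.03 AU on each side
of the injury), umbra (minimum between them, with tie rules), penumbra
prominence, half-maximum injury extent, and distal means. Continuous
recordings are tracked frame by frame with a 40-frame median filter on
the zone locations, and modalities are compared per subject by Spearman's
ρ over distance bins, averaged across subjects with Fisher's z transform.

A synthetic phantom generator (injured-cord scenes with analytic ground
truth, bolus kinetics, benchtop tube phantoms) makes the whole pipeline
testable without animal data.

## Worked example

```r
library(cordflow)

## a phantom recording with known ground truth (umbra at 0 mm,
## penumbras at ±2.0 mm)
scene <- makeScene(seed = 7)
stack <- renderNoncontrast(scene, seed = 8)      # 195 frames @ 39 fps

## non-contrast arm: velocity-index map -> spatial profile -> zones
vmap  <- timeAverageMap(stack)
prof  <- flowProfile(vmap, injuryGeometry(scene))
labelZones(prof)
#> ZoneLabels: umbra 0.05 mm (flow 0.0794)
#>   penumbra rostral -2.05 mm / caudal 1.95 mm, prominence 0.238 / 0.236
#>   distal flow 0.256 / 0.256, injury extent 1.63 mm

## contrast arm: bolus recording -> decay-constant map
cbolus <- renderContrast(scene, seed = 9)        # 150 s bolus
kmap   <- contrastFlowMap(cbolus)                # fit + offset-disk opening
kmap
#> FlowMap [1/s]: 96 x 224 px, 0.05 mm/px, 11648 valid px, max 0.0785

## cross-modality agreement over distance bins
cprof <- flowProfile(kmap, injuryGeometry(scene))
spearmanProfiles(prof, cprof)
#> Spearman rho = 0.984 (p = 6.37e-84, 112 bins)
```

The labeled umbra (0.05 mm) and penumbras (−2.05 / 1.95 mm) sit within
half a bin of the scene's true extrema (0 and ±2.0 mm); the two arms —
one in AU, one in 1/s — rank the distance bins almost identically, which
is exactly the monotone (not linear) agreement the rank correlation is
meant to capture. Flows are in arbitrary units: the velocity index is
monotonically related to velocity but not calibrated to mm/s.

A command-line interface wrapping the same functions ships at
`inst/scripts/cordflow` (subcommands `simulate`, `velmap`, `decaymap`,
`profile`, `zones`, `track`, `compare`).

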