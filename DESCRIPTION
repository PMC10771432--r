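Package: cordflow
Title: Spinal Cord Blood Flow Mapping from Non-Contrast and
    Contrast-Enhanced Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies spinal cord perfusion after contusion injury from
    ultrasound recordings. Converts non-contrast (power-Doppler / SMI type)
    recordings into velocity-index maps and contrast-harmonic microbubble
    bolus recordings into exponential-washout decay-constant maps, bins
    flow by signed distance from a user-drawn injury line into an
    area-adjusted spatial profile, labels the umbra (epicenter), rostral
    and caudal penumbras and distal zones by topographic peak prominence,
    measures the half-maximum injury extent, tracks zones frame-by-frame
    over time, and compares modalities with per-subject Spearman rank
    correlation averaged across subjects by Fisher's z transform. Includes
    a synthetic phantom generator (injured-cord scenes, bolus kinetics,
    benchtop tube phantoms) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'compare.R'
    'contrast.R'
    'cordflow-package.R'
    'io.R'
    'noncontrast.R'
    'profile.R'
    'synthetic.R'
    'zones.R'
    'temporal.R'
    'utils.R'
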