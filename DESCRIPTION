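Package: cardiomap
Title: Cardiac Optical Mapping Analysis and Synthetic Dual Voltage-Calcium Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-channel cardiac optical mapping
    (membrane potential and intracellular calcium): signal conditioning and
    quality masking, per-site action potential and calcium transient duration
    at 80% repolarization, monoexponential calcium-decay time constants,
    beat-to-beat alternans detection with concordant/discordant classification
    and nodal-line extraction, burst-pacing alternans thresholds, isochrone and
    conduction-velocity mapping, conduction-block detection, phase mapping with
    phase-singularity (reentry pivot) tracking, pseudo-ECG rhythm
    classification (premature ventricular beats, ventricular tachycardia and
    fibrillation, inducibility), and paired statistical comparison across
    experimental conditions. Includes a ground-truthed synthetic tissue
    generator built on a two-variable excitable reaction-diffusion model with
    a driven calcium subsystem, infarct scar, restitution-driven alternans,
    focal ectopy and parametric drug effects, so every analysis stage is
    verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
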