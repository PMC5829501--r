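Package: pcmhalo
Title: Quantification of Pericentriolar Material Disassembly from
    Fluorescence Time-Lapse Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the assembly and disassembly of pericentriolar
    material (PCM) in fluorescence time-lapse movies of early C. elegans
    embryos. Implements the annulus-background quantification method: seed
    detection on a Gaussian-blurred frame, local background estimation in a
    band-shaped region between two concentric circles, an adaptive threshold
    (mean + k*sd), seed-connected suprathreshold segmentation, and integrated
    signal intensity as a proxy for PCM mass. Downstream kinetics turn
    per-frame masses into normalized curves aligned by nuclear envelope
    breakdown or by disassembly onset, disassembly rates, percent rate
    reductions between conditions, and persistent-mass fractions. A
    ground-truthed synthetic movie generator (two diffraction-blurred
    centrosome foci with programmed mass kinetics inside a noisy ellipsoidal
    embryo, plus two-channel fixed-embryo spot images for ratiometric
    immunofluorescence) makes every step of the analysis testable without raw
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tibble,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
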