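Package: axonquant
Title: Quantification of Retinal Axon Sorting, Growth-Cone Dynamics, and
    RNP-Granule Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reproducible quantification pipeline for fluorescence-microscopy
    studies of retinotopic axon sorting in the optic tract. Computes the
    missorting index and projection areas from two-channel tract images,
    classifies RNP-granule tracks into anterograde, retrograde and
    static/oscillatory motion, measures anterograde flux and contact-aligned
    central/peripheral granule distributions in growth cones, detects and
    scores growth-cone filopodia dynamics, classifies growth-cone/axon
    encounter behaviors (fasciculation, crossing, tracking,
    stalling/retraction), and computes Manders colocalization, puncta
    association and proximity-ligation-assay dot statistics. A seeded
    synthetic-data module generates images, masks, tracks and encounter
    trajectories with machine-readable ground truth so every analysis stage
    can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    mgcv,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
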