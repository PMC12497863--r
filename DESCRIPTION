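Package: SynapseKinetics
Title: Contact Kinetics, Membrane-Transfer and Crosstalk Screening for
    CD8 T / NK Cell Interactions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of cytotoxic lymphocyte interactions in
    time-lapse microscopy. Segments tracked cell trajectories into
    pre-contact, contact and post-contact phases, computes per-phase
    velocities and deceleration ratios, and a per-frame Speed-Distance
    Index with time-binned summaries and pixel-distance proximity
    classification. Segments fluorescent channels, links centroids into
    tracks and quantifies transferred membrane fragments (trogocytosis) as
    pixel counts within recipient cell masks. Screens ligand-receptor pair
    tables against per-cell-type TPM expression with an all-subunits
    complex rule, and normalizes phospho-flow readouts as co-culture to
    monoculture fold changes. A seeded synthetic-data generator provides
    tracks, image stacks, expression and flow tables with full ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, SingleCell, Software
RoxygenNote: 7.3.3
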