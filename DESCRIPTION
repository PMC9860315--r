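Package: wormforage
Title: Worm Foraging Behavior, Plate Assays and Oocyte Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of Caenorhabditis elegans foraging behavioral
    states and of ligand-gated ion channel pharmacology in Xenopus oocytes.
    Provides a trajectory post-processing pipeline (track filtering, gap
    interpolation, rolling-mean smoothing, curvature-based reorientation
    detection, per-worm behavioral metrics), plate-level assay statistics
    (dispersal zone-density ratio from thresholded plate images, food-leaving
    probability, quadrant chemotaxis index, patch-occupancy time courses),
    two-electrode voltage-clamp analysis (peak extraction, per-oocyte
    normalization, three/four-parameter Hill EC50/IC50 fitting with
    information-criterion model selection, reversal-potential and ion-shift
    extraction, multi-pulse ratios), a monoisotopic mass utility, and seeded
    synthetic-data generators for every input so the whole pipeline is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    EBImage,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
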