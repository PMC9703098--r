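Package: aggrekin
Title: Nucleation-Growth Kinetics and Single-Aggregate Image Analysis for
    p53 Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the aggregation of full-length p53 at
    physiological concentrations: simulation and one-parameter fitting of a
    classical nucleation-growth-dissociation kinetic model, calibration of
    thioflavin-T (ThT) fluorescence traces to aggregate mass via measured
    solubility, diffraction-limited single-aggregate image analysis with
    signal-to-background-ratio (SBR) corrected intensities, Proteinase-K
    sensitivity classification, supported-lipid-bilayer hole quantification,
    and standard-curve monomer quantitation.  Includes seeded synthetic-data
    generators (model-based ThT traces, PSF-blurred particle image stacks
    with ground truth, matched before/after digestion pairs, bilayer images,
    blot standards) so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
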