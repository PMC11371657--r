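Package: twitchtax
Title: Quantifying Spatial Chemotaxis of Surface-Attached Twitching Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pili-based ('twitching') chemotaxis of
    surface-attached rod-shaped bacteria in microfluidic gradient experiments.
    Provides models of microfluidic concentration fields (Taylor-Aris
    dispersion fronts, dual-flow diffusive cross-channel gradients, smooth
    concentration switching) and their design arithmetic; detection and
    tracking of cells in time-lapse image stacks; trajectory kinematics with
    motility classification and reversal detection; quantification of polar
    fluorescent-fusion localization along the cell body; rule-based
    classification of repolarization events in stationary cells exposed to
    alternating gradients; exact Poisson and binomial count inference; and a
    synthetic time-lapse microscopy generator with complete ground truth so
    that every stage of the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    signal,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
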