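Package: fiberAlign
Title: Protein Fiber Alignment in Engineered Tissue Constructs from
    Polarized Raman Spectroscopy, Fiber Images and Continuum Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the direction and extent of structural protein
    alignment in engineered tissue constructs from three complementary
    modalities. A polarized Raman spectroscopy (PRS) branch preprocesses
    polarization-resolved spectra (iterative polynomial baseline removal,
    Savitzky-Golay smoothing, standard normal variate normalization,
    spectral cropping), projects them onto a master PC1 loading derived
    from highly aligned reference tissue, and fits a sinusoid of the PC1
    score against polarization angle to obtain an amplitude alignment
    metric and alignment angle. A discrete-fiber branch computes the
    orientation-tensor mean fiber axis, the alignment index
    S = 2<cos^2 theta> - 1 and axial circular statistics from fiber tables.
    A continuum branch solves a plane-stress compressible neo-Hookean
    finite-element model of cell-mediated gel contraction, fits the
    shrinkage strain to a measured area change, and converts the local
    deformation gradient into ellipse-based alignment factors and an
    equivalent alignment index from embedded fibers, bridging the two
    measurement modalities. Seeded synthetic-data generators emulate the
    statistical structure of the raw spectra and fiber images so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    signal,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
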