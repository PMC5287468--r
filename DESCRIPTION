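Package: poreSym
Title: Morphometry, Rotational Symmetry and Spatial Statistics of
    Pore-Like Membrane Complexes in Electron Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative 2D analysis of nuclear-pore-like
    complexes on membrane sheets imaged by transmission electron microscopy:
    a synthetic-micrograph generator with full ground truth (parametric
    ring/plug pore models on hard-core point patterns), TIFF/MRC image input
    and output, annulus matched-filter pore detection and areal density
    estimation, radial-profile ring morphometry, Markham rotational-symmetry
    reinforcement with tilt/ellipticity correction and an angular power
    spectrum cross-check, and immunogold distance-association counting with
    a permutation null.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    tools,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Visualization, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'goldassoc.R'
    'io.R'
    'morphometry.R'
    'pipeline.R'
    'poreSym-package.R'
    'poredetect.R'
    'symmetry.R'
    'synthgen.R'
    'utils-internal.R'
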