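Package: helixlattice
Title: Helical Lattice Analysis for PB1-Domain Filaments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of helical protein filaments of the kind
    formed by self-polymerizing PB1 domains (p62/SQSTM1, plant NBR1).
    Provides exact helical-symmetry algebra (rise/twist/pitch conversions,
    equivalent asymmetric-unit notations, Bessel selection rule, symmetry
    expansion), synthetic filament/tomogram/calorimetry data generators with
    ground truth, power-spectrum layer-line detection and indexing to
    candidate symmetries, grid-search symmetry determination by spectrum
    cross-correlation, Fourier shell correlation utilities, inter-subunit
    salt-bridge mapping on expanded lattices, tomogram filament morphometry
    (thresholding, 3D skeleton tracing, width/length distributions), and
    one-site isothermal titration calorimetry and thermal-melt fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    bio3d,
    minpack.lm,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
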