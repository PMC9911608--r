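Package: fretclem
Title: Correlative FLIM-FRET and Platinum-Replica EM Analysis of Clathrin Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for FRET-CLEM, the correlative analysis of
    fluorescence-lifetime FRET images and platinum replica electron micrographs
    of clathrin-coated structures. Provides IRF-convolved bi-exponential TCSPC
    decay models and Poisson maximum-likelihood fitting, amplitude-weighted and
    center-of-mass lifetime summaries, FRET efficiency estimation, geometric
    multi-acceptor FRET simulation over clathrin lattice sites with heavy-chain
    occupancy models, membrane-plane dark-quencher (DPA) axial distance
    modelling, affine FLIM-to-EM registration from fiducials, per-structure ROI
    lifetime statistics with per-cell flat-lattice normalisation, EM lattice
    morphometrics, and a seeded synthetic-data generator producing matched
    FLIM/EM scenes with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
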