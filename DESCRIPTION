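Package: dimerlens
Title: Contact, Secondary-Structure and Dimerization Analysis of Coarse-Grained alpha-Synuclein Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse two-chain Calpha-trace conformational ensembles of
    the intrinsically disordered protein alpha-synuclein in the early stage of
    dimerization. Implements dimer classification from intermolecular Calpha
    contacts, curvature/torsion-based secondary-structure assignment with
    beta-sheet pairing and orientation, detection of fibril-like native
    (same-index) intermolecular contacts and of pre-fibrillar dimers, effective
    free-energy landscapes over contact counts with local-minimum extraction,
    Gaussian-mixture clustering of the radius of gyration, approximate FRET
    efficiencies, AFM-style contour-length estimates, and Chou-Fasman beta-sheet
    propensity profiles. A seeded synthetic-ensemble generator plants helices,
    strands and in-register intermolecular beta-sheet interfaces so that every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    mclust,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
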