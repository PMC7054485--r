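Package: fibrilMD
Title: Coarse-Grained Molecular Dynamics of Strain-Induced Fibril Formation in Micellar Hydrogels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and deforms a coarse-grained micellar hydrogel network of
    alternating acrylic-acid and poly(ethylene glycol) repeat units solvated by
    single-bead water, integrates the equations of motion with a Langevin
    thermostat under rate-controlled constant-volume uniaxial stretching, and
    quantifies strain-induced fibrillogenesis: single-linkage physical-cluster
    detection, Delaunay cluster volume fraction and network damage, four-class
    short-flexible-chain taxonomy with class-transition bookkeeping, bundle and
    fibril detection with rotation and twist tracking, nematic order parameter
    P2, z-axis layer profiles, and autocorrelation relaxation times with
    Weissenberg-number regime classification. Includes a minimal four-chains
    model for controlled studies of chain alignment, fibril formation and
    twist stability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
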