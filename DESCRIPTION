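Package: enmox
Title: Elastic Network Modes and Interface Statistics for Enzymes on Carbon Nanostructures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: All-atom distance-weighted elastic network modelling and
    normal-mode analysis of enzymes immobilized on carbon nanomaterials.
    Builds graphene sheets and single-walled carbon nanotubes from chiral
    indices, assembles mass-weighted Hessians for distance-weighted spring
    networks, solves for natural frequencies and modal shapes (dense and
    sparse Lanczos paths), compares modes across bulk and immobilized
    conditions, computes trajectory interface statistics (superposed RMSD,
    radius of gyration, contacts, minimum distance, tail averaging), and
    estimates apparent heterogeneous electron-transfer rates from
    scan-rate-dependent cyclic-voltammetry peak separations (Laviron
    analysis). Includes synthetic generators for every input so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
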