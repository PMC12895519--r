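Package: napltaxis
Title: Bacterial Chemotaxis to a NAPL-Water Interface Under Shear Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multiscale analysis of Pseudomonas putida chemotaxis toward
    naphthalene dissolving from a nonaqueous-phase-liquid (NAPL) interface
    in a microfluidic channel under laminar shear flow.  Provides a
    finite-volume solver for the coupled attractant advection-diffusion
    and Keller-Segel-type bacterial transport equations with a
    receptor-law tanh chemotactic drift, least-squares estimation of the
    apparent chemotactic sensitivity coefficient from normalized density
    profiles, a stochastic run-reverse agent-based model with
    stimulus-modulated reversal frequency, trajectory statistics for
    TrackMate-style particle tracks, and a synthetic-data module that
    emulates the microfluidic observations so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
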