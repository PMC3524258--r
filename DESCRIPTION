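Package: raftsig
Title: Compartmental Kinetic Modeling of FcERI Signaling with Transient Lipid Rafts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based generation and deterministic simulation of a
    compartmental (lipid raft / nonraft) mass-action model of early
    high-affinity IgE receptor (FcERI) signaling in RBL-2H3 cells,
    extending the membrane-proximal network of Faeder et al. (2003)
    with LAT, Grb2, a monovalent hapten and a two-compartment membrane
    in which rafts are transient structures with a finite mean lifetime.
    Includes analytic raft biophysics (partition-coefficient to
    exchange-rate conversion, the two-dimensional diffusion-limited
    capture rate for transient disk traps, and the minimum physically
    consistent raft lifetime), in-silico dose-response, hapten-inhibition
    dephosphorylation, raft-lifetime and Lyn palmitoylation-mutation
    experiments, and synthetic dephosphorylation datasets with
    grid-search recovery of the raft protection factor alpha.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
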