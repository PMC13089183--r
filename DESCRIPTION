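Package: rssmet
Title: Kinetic, Energetic, and Geometric Analysis of Reactive Sulfur Species Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for S-adenosylmethionine-dependent methylation of
    reactive sulfur and selenium species by thiopurine S-methyltransferase
    (TPMT). Fits single-substrate Michaelis-Menten kinetics and a piecewise
    dual-substrate model with a breakpoint concentration C1 that partitions
    substrate between an in-situ-formed persulfide branch and a free-H2S
    branch; identifies stable ligand-binding conformations from fragment
    pair-interaction-energy (PIE) matrices by agglomerative clustering with
    Tukey-Kramer multiple comparisons and compact letter displays; and scores
    steric accessibility of nucleophilic attack from per-frame trajectory
    geometry (attack distance, alignment angle theta, hindrance angle phi).
    A synthetic-data module generates kinetic tables, planted-cluster PIE
    matrices, and coordinate trajectories with known ground truth so every
    stage is testable without wet-lab data or simulation engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
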