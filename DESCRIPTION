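Package: hsascreen
Title: Screening Human Serum Albumin Ligands That Modulate Amyloid-Beta Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico screening pipeline for low-molecular-weight ligands
    of human serum albumin (HSA) that may modulate HSA affinity for monomeric
    amyloid-beta peptide. Provides a drug-repurposing filter cascade
    (molecular mass, water solubility, blood-brain-barrier penetration,
    plasma concentration, disease-literature support, fatty-acid exclusion),
    dynamic-time-warping clustering of predicted HSA binding sites with
    residue-frequency ranking of cluster representatives, equilibrium
    occupancy of HSA binding sites with and without ligand depletion, and
    simulation plus nonlinear least-squares fitting of two-site
    (heterogeneous-ligand) surface plasmon resonance sensorgrams with
    free-energy and fold-change reporting. Synthetic-data generators make
    every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
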