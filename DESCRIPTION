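Package: tcmflavor
Title: Linking Binding-Site Class of Metabotropic Glutamate Receptors to
    Traditional Chinese Medicine Flavors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline connecting the binding-site class
    (orthosteric versus allosteric) of metabotropic glutamate receptors
    (mGluRs) to the five-flavor taxonomy of traditional Chinese medicines
    (TCMs). Provides pharmacophore-model selection by summed competition
    ranks over intrinsic model parameters, Pareto dominance ranking, 3D
    pharmacophore feature matching, a drug-likeness and blood-brain-barrier
    filter cascade, docking-validation statistics (paired-atom RMSD and the
    Spearman correlation between experimental affinity rank and docking
    score), per-group herb tracing with flavor and traditional-effect
    frequency analysis, a permutation test for flavor enrichment, and export
    of the target-flavor-function network. A seeded synthetic library
    generator emulates a TCM compound database with plantable flavor-site
    associations so that every stage is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
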