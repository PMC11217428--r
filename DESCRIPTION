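Package: voxtrace
Title: De Novo Protein Backbone Tracing from Cryo-EM Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds de novo C-alpha backbone models from cryo-EM density maps.
    A transformer-based voxel classifier assigns backbone-atom and amino-acid
    classes to every voxel of a density grid; predicted C-alpha voxels are
    clustered into atoms; a fully connected hidden Markov model over the atoms
    is aligned to the protein's chain sequences with a no-repeat Viterbi
    decoder to produce an ordered backbone; logistic-regression confidence
    scores and reference-based quality metrics (3 Angstrom C-alpha matching,
    recall/precision/F1, match and quality scores) complete the pipeline.
    Includes a synthetic-data generator so every stage is testable without
    experimental maps or trained weights.
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
    ggplot2,
    generics,
    Biostrings,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
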