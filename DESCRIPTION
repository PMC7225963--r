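Package: casptrace
Title: Conservation-Based Ranking of Apoptotic Caspase Cleavage Targets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Ranks human apoptotic caspase cleavage sites by their conservation
    across vertebrates. Anchors each cleavage site in ortholog sequence segments
    by minimum Hamming distance around the P1 aspartate, aggregates P1 identity
    and octamer-distance statistics, scores the structural context of the site
    (coil prevalence from Q3 secondary-structure strings) and its hydrophobicity
    context (shifted prevalence on the cyclohexane-to-water transfer free-energy
    scale), classifies the fate of the nascent N-terminus of the C-terminal
    fragment under the Arg/N-degron pathway, and applies a five-criterion filter
    with reference-set validation. Includes species dendrograms from concatenated
    cleavage-site octamers compared with Baker's Gamma, and a seeded synthetic
    corpus generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    methods,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
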