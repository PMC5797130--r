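Package: lexiviable
Title: Viable Clusters and Explosive Growth in Multiplex Lexical Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the mental lexicon as a multiplex network:
    detection of viable clusters (word sets connected within every layer taken
    in isolation), simulation of vocabulary growth under normative and
    attribute-based acquisition orderings with detection of explosive
    transitions in the size of the largest viable cluster, topology and
    attribute randomisation null models, psycholinguistic group statistics
    with Monte Carlo sample-size and degree corrections, core-periphery link
    densities, and closeness-based robustness experiments under targeted word
    removal. Includes a synthetic planted-core multiplex generator with
    copula-correlated psycholinguistic attributes so that every stage of the
    pipeline can be exercised without access to licensed lexical datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
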