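Package: phylOG
Title: Phylogeny-Based, Noise-Tolerant Delineation of Orthologous Groups
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Delineates hierarchically consistent, evolutionarily dated
    orthologous groups (OGs) from gene trees with species-tagged leaves.
    Gene trees are prepared by minimum-variance rooting and long-branch
    leaf removal, every internal node is dated with the last common
    ancestor of its species and classified as a speciation or duplication
    event using the species-overlap score with a two-step taxonomic
    outlier exclusion, and retained duplication nodes are converted into
    nested OGs dated at their taxonomic level. Includes alignment-column
    trimming by gap content, duplication-rate and reference-group
    F-score benchmarking utilities, and a seeded gene-family simulator
    (duplication, loss, leaf transplants, branch inflation) providing
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    phytools,
    Biostrings,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
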