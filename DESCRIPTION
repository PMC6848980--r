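Package: modcoupler
Title: Inter-Module Coupling Analysis of Disease and Drug-Target Protein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs weighted protein association networks for a disease
    gene set and a drug (herbal formula) putative-target set, dissects each
    network into dense modules with a reimplementation of the MCODE density
    clustering algorithm, merges the two networks over a background
    interaction table, and quantifies inter-module connectivity with an
    exact hypergeometric test and a coupling score (twice the shared-node
    count plus the summed confidence weights of cross-module edges).
    Includes hypergeometric pathway enrichment with KEGG-style category
    roll-ups, a bridgeness report over groups of disease and drug modules,
    synthetic planted-module network generators for validation, and a
    deterministic end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
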