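Package: kdnet
Title: Key Driver Analysis on Directed Causal Gene Networks
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and prioritizes key driver genes (predicted master
    regulators) of disease gene sets on directed causal gene networks.
    Implements cross-cohort core-module derivation from coexpression module
    collections, seed projection onto networks by path-length neighborhoods,
    h-layer key driver analysis with enrichment maximization and global/local
    driver classification, composite rank aggregation of drivers across
    disease-evidence gene sets, validation of driver predictions against
    perturbation signatures, cis/trans eQTL detection with a permutation null,
    and polygenic risk scoring. Ships a synthetic-data generator (linear
    structural equation models on sparse hub DAGs, knockout signatures, cis
    genetic effects) with planted ground truth for end-to-end calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
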