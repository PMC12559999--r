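Package: radils
Title: Gene-Tree Conflict, Anomaly-Zone and Quartet Analytics for Rapid
    Radiations Under the Multispecies Coalescent
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify phylogenomic conflict in rapid radiations and
    to separate incomplete lineage sorting (ILS) from reticulate evolution.
    Classifies gene trees against species-tree bipartitions (strong/weak
    support and conflict), regresses conflict proportions on internode
    length, evaluates the anomaly-zone boundary a(x) and scans coalescent-unit
    species trees for anomalous internode pairs, counts quartet topologies
    across gene trees with star and T3 likelihood-ratio tests under the
    multispecies coalescent, exports NANUQ quartet distances for
    splits-network software, clusters genomes from pairwise average
    nucleotide identity (ANI) tables with gap detection, and summarises
    symbiotic partner sharing between co-occurring and non-co-occurring
    specimen pairs. Includes a multispecies-coalescent simulator with
    gene-tree estimation-error and pseudo-support models, plus ANI-table and
    specimen-table generators, so every stage can be exercised on synthetic
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
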