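Package: skimbin
Title: Skim-Sequencing Genotyping and Bin Mapping for Biparental Inbred
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genotyping pipeline for large biparental recombinant inbred
    line (RIL) populations sequenced at very low (skim) coverage.
    Filters high-depth parental variant calls into a segregating key,
    codes sparse progeny calls by parental origin, builds 1-Mb consensus
    bin genotypes, locates crossover breakpoints with a paired
    sliding-window roaming score, imputes missing site genotypes with a
    parental-origin hidden Markov model validated by hold-out masking,
    estimates genetic-map statistics (Haldane-Waddington RIL correction,
    Kosambi distances), and performs simplified trait mapping
    (single-marker LOD scan with permutation thresholds, digenic
    epistasis, per-site association with FDR control). A configurable
    simulator generates synthetic RIL skim-seq datasets with known truth
    so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
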