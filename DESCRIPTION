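Package: diatomRing
Title: Inter-Laboratory Proficiency Testing for Diatom DNA Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for cross-laboratory proficiency tests and
    method-comparison experiments in DNA-metabarcoding-based freshwater
    biomonitoring with benthic diatoms. Expands ring-trial experimental
    designs into sample manifests with sequencing-inclusion rules, filters
    and aggregates taxon abundance tables, computes Hill-number diversity
    and coefficient-of-variation summaries, trait-weighted diatom quality
    indices (IPS- and IBD-type) with ecological status classes, z-score and
    Youden-plot proficiency statistics with pass/fail verdicts, taxon
    detection thresholds, anomaly diagnosis (sample swaps, two-community
    mixtures), and community-level variance partitioning (Bray-Curtis,
    PERMANOVA, MRPP, nMDS, Kruskal-Wallis). Includes a seeded multi-
    laboratory community simulator with per-lab systematic bias, replicate
    noise, dropout and injected anomalies, so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    vegan
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AbundanceTable.R'
    'community_stats.R'
    'design.R'
    'diversity.R'
    'indices.R'
    'io.R'
    'pipeline.R'
    'preprocess.R'
    'proficiency.R'
    'synthetic.R'
    'traits.R'
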