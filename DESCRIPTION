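Package: ironmeta
Title: Iron-Acquisition Gene Profiling for Metagenomic Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for profiling iron-acquisition genes in assembled
    metagenomes. Implements thresholded lowest-common-ancestor (LCA) taxonomic
    classification of ORFs from tabular protein-homology hits, consensus contig
    taxonomy, per-genome copy-number normalization against universal single-copy
    marker genes, categorization and quantitation of iron transport and
    siderophore synthesis genes, rule-based presence/absence calling of
    siderophore biosynthesis pathways, and a seeded synthetic-community
    generator that emulates a phytoplankton-bloom time series with a
    siderophore producer/cheater split, so every stage can be exercised and
    verified at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
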