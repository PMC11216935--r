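Package: pulcensus
Title: Protein Domain Census and Polysaccharide Utilization Locus
    Co-Localization from Gene Annotation Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines KEGG/UniProt-style gene annotation records for a target
    protein domain (DUF1735, BACON, BACON_2, or any Pfam-style name) and
    summarizes where and how it occurs. Filters domain hits at an E-value
    cutoff, canonicalizes per-protein domain architectures with overlap
    grouping, infers each genome's locus-tag numbering step (1, 5, or 10),
    scans a +/-5 gene window around every target-domain gene for SusD
    evidence (KO K21572, SusD-like/RagB domains, or name matches) to call
    polysaccharide utilization locus (PUL) membership, classifies susE/F/G-
    like positions, and emits architecture, copy-number and taxonomy census
    tables. A synthetic genome generator with a ground-truth manifest makes
    the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    Biostrings,
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
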