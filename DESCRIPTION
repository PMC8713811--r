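Package: wcategory
Title: Signature-Based Classification and Comparative Genomics of MHC-Like Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative sequence analysis of major histocompatibility
    complex (MHC) chains, built around diagnostic-residue signatures that
    separate class I heavy chains, beta-2 microglobulin, class II alpha/beta
    chains, and the W-category alpha/beta chains (an MHC group with class II
    domain architecture but class I interdomain sequence features). Provides a
    declarative signature schema over canonical domain position frames, domain
    segmentation and frame mapping of protein chains, per-chain classification
    with an evidence trail, typing of the three class I interdomain interfaces,
    neighbor-joining phylogenetics with bootstrap bipartition support for
    testing the WA-alpha2/beta-2-microglobulin clustering, per-column
    conservation profiling, detection of head-to-head WA/WB gene pairs in
    genome annotations, and a synthetic-data generator that makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
Collate: 
    'wcategory-package.R'
    'domain_mapper.R'
    'classifier.R'
    'phylo.R'
    'conservation.R'
    'genomic_pairs.R'
    'pipeline.R'
    'schema.R'
    'simulate.R'
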