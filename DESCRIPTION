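Package: plastomics
Title: Comparative Chloroplast Genome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated plastid (chloroplast)
    genomes: detection of the quadripartite LSC-IRb-SSC-IRa structure and
    genome summary statistics, codon-usage bias (RSCU), microsatellite (SSR)
    and long forward/palindromic/reverse/complement repeat scanning,
    IR-junction gene offset reporting, sliding-window nucleotide diversity
    with hypervariable-region merging, and pairwise Ka/Ks (NG86) selection
    analysis. Includes a synthetic plastome generator with ground-truth
    manifests so every stage can be validated without downloading records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
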