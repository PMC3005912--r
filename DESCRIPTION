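Package: orthoSplice
Title: Transcript-Level Refinement of Orthologue Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Refines one-to-one orthologue groups at the transcript level.
    Protein isoforms of an orthologous gene pair are multiply aligned with a
    built-in progressive affine-gap aligner (or a user-supplied alignment), an
    alignment-projected similarity score is computed for every isoform pair,
    and each group is partitioned into transcript sub-clusters by an
    InParanoid-style anchor-pair algorithm. Sub-clusters are verified with two
    independent measures: the Hamming distance between binary InterPro-style
    functional signature vectors, and the difference in counts of predicted
    intrinsically disordered regions after length filtering and gap merging.
    Intra- versus inter-cluster difference distributions are compared with
    Wilcoxon rank-sum tests. A seeded synthetic-data generator emulating
    exon-skipping isoforms makes the whole pipeline testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    mclust,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
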