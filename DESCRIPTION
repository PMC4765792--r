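Package: polymir
Title: Small RNA Discovery, Target Validation and Subgenome Evolution in
    Allopolyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis toolkit for microRNA (miRNA) biology in
    allopolyploid plant genomes. Discovers MIRNA loci from collapsed
    small-RNA libraries by hairpin folding and miRNA/miRNA* duplex
    criteria, classifies them as conserved or novel against a reference
    set of known mature sequences, predicts targets by complementarity
    scoring with degradome (PARE) cleavage validation, establishes locus
    orthology between an allotetraploid and its progenitor genomes by
    microsynteny of flanking protein-coding genes, calls locus gains and
    losses, and quantifies subgenome expression partitioning together
    with additive versus non-additive heredity in derived lines. Ships a
    synthetic-data generator with a fully known planted truth so that
    every stage can be exercised and scored end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
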