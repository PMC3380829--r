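Package: censat
Title: Reference-Free ChIP-Seq Discovery of Centromeric Satellite Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies and characterizes repeat families associated with
    centromeric chromatin from CenH3 ChIP-seq data without a genome assembly.
    Short ChIP and input reads are quality-trimmed, matched against
    low-coverage genomic reads under a bounded-difference model (up to two
    mismatch/indel events, at most four indel bases), and enrichment is
    computed as the ratio of ChIP to input read proportions either per
    abundance-ranked similarity cluster or per reference read.  Reads with at
    least 10-fold enrichment are clustered by mutual similarity into repeat
    families, which are then profiled: a representative contig is assembled,
    the satellite monomer length is inferred from sequence periodicity,
    head-to-tail tandem organization is verified, AT content is measured, and
    families are classified as satellite or LTR retroelement.  Includes a
    truth-annotated synthetic genome generator emulating a large AT-rich
    plant genome with many tandem-satellite families and a dispersed
    centromeric retrotransposon, plus quantification helpers converting
    genome proportions and cytological measurements into Mbp.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
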