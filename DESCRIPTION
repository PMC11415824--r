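Package: mevcall
Title: Mobile Element Insertion and Deletion Calling from Long-Read Alignments
Version: 0.1.0
Authors@R:
    person("MEV", "Maintainers", email = "maintainers@mevcall.dev", role = c("aut", "cre"))
Description: Detects and genotypes mobile element variants (MEVs) of the Alu,
    L1 and SVA retrotransposon classes from coordinate-sorted long-read
    alignments. Insertion and deletion signatures are harvested from CIGAR
    strings and split-read placements, clustered per locus, collapsed into a
    consensus sequence, and classified against a mobile element template
    library by a banded affine-gap Smith-Waterman first round followed by a
    k-mer prescreen and a pluggable second-round classifier for fragmented
    events. Calls are genotyped from supporting versus reference-spanning
    read counts and written as VCF 4.2. A deterministic diploid genome and
    long-read simulator with truth VCF output, plus a benchmarking module
    (precision/recall/F1, FDR, trio Mendelian discordance), make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    GenomicAlignments,
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
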