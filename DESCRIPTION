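Package: mosaicbench
Title: Benchmarking Ultra-Low-VAF Mosaic Variant Detection with Cell-Line Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for constructing and using cell-line-mixture truth sets for
    benchmarking somatic mosaic SNV and indel callers at variant allele
    fractions below 5%. Implements dual-platform truth-set construction
    (short-read candidate merging with long-read orthogonal validation),
    iterative negative-control construction, discovery of culture-derived
    mutations from multi-replicate call sets, three-way (true positive /
    false positive / masked) evaluation stratified by VAF bin and genomic
    context, expected-VAF arithmetic for designed mixtures, and a binomial
    allele-sampling model for multi-replicate designs. A synthetic-data
    module generates mixtures, pileups and caller call sets with known
    structure so every stage can be exercised without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
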