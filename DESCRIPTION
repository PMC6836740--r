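Package: pollenphase
Title: Gamete-Based Haplotype Phasing with Single-Pollen-Cell Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phases a diploid genome into its two haplotypes using
    single-cell genotype calls from haploid pollen. Each SNP on a long
    genomic fragment (BAC or contig) is summarized as a binary barcode
    over the pollen cells; fragments are anchored to reference
    chromosomes by breadth of coverage, assigned to haplotype families by
    hamming-distance chaining of barcode profiles, meiotic crossovers are
    called from persistent barcode switches along each cell, and mosaic
    gene assemblies in a collapsed reference are detected by three-way
    sequence comparison. A built-in simulator of diploid genomes,
    meiosis, and single-cell amplification artifacts provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    vcfR,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
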