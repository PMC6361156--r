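Package: enumap
Title: Mapping-by-Pedigree Analysis for ENU Mutant Pedigrees
Version: 1.0.0
Authors@R:
    person("R.", "Developer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for forward-genetic mapping of
    recessive point mutations in multi-generation animal pedigrees produced
    by ENU (N-ethyl-N-nitrosourea) mutagenesis. Provides a pedigree and
    genotype simulator with recombination (Haldane model), SNP-array quality
    control, the family-based transmission disequilibrium test with maxT
    permutation correction and significant-region calling, a stepwise exome
    variant filter cascade with recessive co-segregation, exonic splicing
    enhancer position-weight-matrix scanning with allele contrast, and
    exon-skipping consequence prediction including RT-PCR amplicon and
    minigene product arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    digest,
    optparse,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
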