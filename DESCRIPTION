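Package: allelign
Title: Allele-Specific Epigenomic Analysis with INDEL-Aware Diploid
    Pseudogenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Engine for allele-specific analysis of whole-genome bisulfite,
    ChIP and RNA sequencing data from F1 hybrids and phased individuals.
    Builds a diploid pseudogenome from a reference and phased SNVs plus
    short INDELs, records the resulting coordinate alterations in a
    block-based refmap index, classifies sequencing fragments aligned to
    the diploid genome as haplotype-specific or non-allelic by alignment
    uniqueness, calls per-CpG per-allele methylation from bisulfite
    alignments, projects allelic signal back onto reference coordinates,
    and summarises allelic imbalance, reference bias and false-positive
    diagnostics over regions of interest. Ships a synthetic F1-hybrid data
    generator (reference genomes, phased variants, genomic, bisulfite and
    enrichment-style paired-end reads with complete per-fragment truth) so
    every stage can be exercised without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
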