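Package: devilclone
Title: Clonal Genomics of a Transmissible Cancer and Its Host
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the genomes of clonally transmissible
    cancers and their host species, motivated by devil facial tumour
    disease (DFTD) in the Tasmanian devil. Implements kmer-spectrum and
    flow-cytometric genome-size estimation, assignment of assembly
    contigs to chromosomes from flow-sorted chromosome sequencing
    libraries with detection of chimeric (misassembled) contigs,
    quality filters for substitution, indel, structural-variant and
    copy-number candidates, four-genome set algebra reconstructing the
    founder animal's germline and somatic-enriched variant sets,
    mutation-spectrum and nonsynonymous/synonymous statistics, perfect
    phylogeny reconstruction of clonal genealogies from binary somatic
    genotype matrices, regional genotype-frequency trajectories with
    selective-sweep flagging, classification of multi-tumour hosts, and
    mitochondrial haplotype grouping with a horizontal-transfer test.
    A synthetic cohort generator with machine-readable truth records
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    tools,
    Biostrings,
    ape
Suggests:
    vcfR,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
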