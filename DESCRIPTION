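Package: rohscan
Title: Runs of Homozygosity Detection and Genomic Inbreeding for SNP-Array Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of runs of homozygosity (ROH) in diploid SNP-array
    genotypes with a PLINK-style scanning-window algorithm, quality control
    including an exact Hardy-Weinberg test, genomic inbreeding coefficients
    (F_ROH overall, per length class and per chromosome), ROH island/hotspot
    mapping with gene counts and recombination rates from a genetic map, and
    TMRCA-based classification of ROH genetic lengths. Includes a
    synthetic-genotype generator with planted autozygous tracts so every
    stage of the pipeline is testable against known truth, and
    readers/writers for PLINK text (PED/MAP) and binary (BED/BIM/FAM)
    formats.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
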