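Package: kaspcall
Title: Control-Anchored KASP Genotype Calling and Allele-Specific
    Occupancy Quantitation for CRISPR Clone Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for scarless CRISPR clone screening with
    competitive allele-specific PCR (KASP) endpoint genotyping. Reads and
    validates two-channel fluorescence plate tables, calls clone genotypes
    against genotype-control clusters (including no-amplification wells
    caused by NHEJ alleles, half-signal compound clones and intermediate
    mixed-population wells), quantitates allele-specific transcription
    factor occupancy from ChIP and input DNA (ChIPnQASO), determines the
    mutant-allele limit of detection from titration series, computes
    T7-endonuclease indel fractions, genotype frequency tables and allelic
    efficiencies, and classifies merged amplicon reads into HDR, NHEJ and
    wildtype outcomes. A synthetic-data generator emulates the fluorescence
    and sequencing instruments so that every stage can be exercised and
    calibrated without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
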