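Package: clonsel
Title: Clonal Selection Analysis of Paired Tumor RNA-Seq Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects clonal selection of somatic variants between paired
    drug-sensitive and drug-resistant tumor samples from transcriptome
    sequencing. Builds a merged variant table from per-sample allele counts,
    applies an annotation-driven inclusion filter (COSMIC, dbSNP, population
    allele frequency, SIFT/PolyPhen-2 deleteriousness, segmental duplications),
    classifies variants as positively or negatively selected versus ancestral
    with a Fisher exact test on alternative allele ratios, estimates regional
    ploidy and allelic imbalance from heterozygous-site allele ratios, and
    calls differentially expressed genes between two libraries without
    replicates. A synthetic-data generator with known clonal structure makes
    every stage testable end to end, and a paired-read overlap merger avoids
    double-counting overlapping mates from short RNA fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
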