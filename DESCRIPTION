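Package: germid
Title: SNP Fingerprinting and Germplasm Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for evaluating tree germplasm panels from
    genome-wide SNP genotypes: hard-filter and population-genetic quality
    screening of variant calls, per-locus and per-group genetic diversity
    indices (Na, Ne, Ho, He, PIC, Shannon H', Nei), phenotypic trait
    summaries and membership-function scoring, genotype and trait principal
    component analysis, UPGMA clustering, composite linkage-disequilibrium
    decay, Evanno delta-K model selection, single-marker general linear
    model association scans, greedy selection of a minimal core SNP set
    that uniquely fingerprints every accession, and export of per-accession
    DNA fingerprint codes as QR images. Includes a synthetic-panel
    generator emulating a three-population admixed germplasm collection so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
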