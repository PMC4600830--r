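Package: cpgburden
Title: Stratified Rare-Variant Burden Testing with CpG-Site Impact Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control rare-variant burden analysis of a coding
    transcript, with variant consequence and CpG dinucleotide gain/loss
    annotation, per-ancestry minor-allele-frequency filtering, exact 2x2
    association statistics (two-sided Fisher test with conditional
    maximum-likelihood odds ratio and exact confidence interval),
    Mantel-Haenszel stratified combination with Robins-Breslow-Greenland
    intervals, and an exact power search for the number of control alleles
    needed to detect a rare allele. Includes a synthetic cohort generator
    that emulates multi-stratum targeted-sequencing and exome case-control
    studies so the full pipeline is testable without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
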