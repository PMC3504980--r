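Package: triolog
Title: Two-Locus Log-Linear Models for Maternal and Offspring Genotype
    Interactions in Case-Parent Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Log-linear (Poisson regression) analysis of case-parent trios
    genotyped at one locus, with mothers additionally genotyped at a second,
    unlinked locus.  Fits mating-type-stratified models to test
    maternal-by-offspring and maternal-by-maternal genotype interactions
    across the two loci, as well as single-locus maternal-by-offspring
    interaction, using likelihood-ratio tests.  Incompletely genotyped trios
    (missing fathers, missing mothers) are handled with an EM algorithm on
    the observed-data likelihood.  Includes an ascertained-trio simulator
    (multinomial cell sampler plus an individual-level rejection sampler),
    named scenario presets, and a replicate engine for Monte-Carlo type-I
    error and power studies, together with a small command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
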