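Package: plaquescreen
Title: Differential Abundance and Oral Disease Association Screening for
    Subgingival Plaque Microbiomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Statistical analysis of taxon-by-sample count tables from
    subgingival plaque 16S rDNA surveys comparing perinatally HIV-infected
    (PHIV) and perinatally HIV-exposed, uninfected (PHEU) youth: sample and
    taxon exclusion rules, alpha diversity (Shannon, Simpson 1-D) and
    analytic rarefaction, per-taxon negative binomial regression rate ratios
    with Benjamini-Hochberg control, false positive report probability
    (FPRP) and Bayesian false discovery probability (BFDP) noteworthiness
    filtering, logistic regression disease-association models with
    group-by-taxon interaction terms, and a synthetic cohort generator with
    known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    vegan,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    biomformat
Config/testthat/edition: 3
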