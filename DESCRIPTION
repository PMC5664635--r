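Package: famGE
Title: Gene-Environment Interaction Variance-Component Tests for Family Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based tests of SNP-set by environment interaction for
    related individuals under a generalized linear mixed model. The null
    model treats SNP main-effect coefficients as random (equivalent to a
    ridge penalty whose parameter is estimated by REML rather than
    cross-validation) and includes a kinship-structured family random
    effect; the interaction is tested with a variance-component score
    statistic calibrated by a Satterthwaite scaled chi-square. Includes
    the q-degrees-of-freedom fixed-effect score test and the MinP
    single-SNP scan with an effective-number-of-SNPs correction, plus a
    pedigree-based (gene-dropping) simulation engine for type-I-error and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    yaml
Config/testthat/edition: 3
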