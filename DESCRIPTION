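Package: obrisk
Title: Obesity Risk Prediction from Optimized Genetic Risk Scores and
    Gene Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds integrated predictive models of body mass index (BMI)
    and binary weight status from a small SNP panel and microarray gene
    expression profiles. Implements an unweighted genetic risk score
    (mean effect-allele dosage), a greedy backward-exclusion optimizer
    that removes SNPs one at a time to maximize the correlation between
    the risk score and BMI, a two-stage BMI-association scan for gene
    expression with Benjamini-Hochberg correction followed by a greedy
    independence filter, ordinary least squares models of BMI on the
    selected features with an interaction scan, a cross-validated
    support vector machine classifier for weight status,
    allele-specific-expression ANOVA validation, and a seeded
    synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
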