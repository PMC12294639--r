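Package: pwudcohort
Title: EHR Phenotyping of Hospitalizations of People Who Use Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based electronic health record (EHR) phenotyping pipeline for
    identifying hospitalization encounters of people who use drugs (PWUD).
    Combines four evidence domains: urine-toxicology and hepatitis C biomarkers
    (B), ICD-9/ICD-10 diagnosis codes matched by code-family prefix (D),
    medications for opioid use disorder (M), and misspelling-tolerant keyword
    detection over free-text clinical notes using an optimal string alignment
    Damerau-Levenshtein matcher (N). Included encounters are partitioned into
    the sixteen Venn cells of {B,D,M,N}; highly documented (all four domains)
    and minimally documented (keyword-only) groups are compared via chart-review
    positive predictive values with Clopper-Pearson intervals, 2x2 odds ratios
    with Woolf confidence intervals, and adjusted logistic regression. A
    synthetic EMR generator with known ground truth makes the whole pipeline
    testable end to end without access to protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tibble,
    dplyr,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
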