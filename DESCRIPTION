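Package: coldheat
Title: Subtype Discovery for Rheumatoid Arthritis from Symptom, Clinical
    Chemistry and LC-MS Metabolomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discriminating two clinically assigned
    rheumatoid-arthritis subtypes (Cold and Heat) from mixed-measurement-level
    data. Implements forced-classification nonlinear principal component
    analysis with optimal scaling (nominal, ordinal and spline analysis
    levels) for questionnaire and clinical-chemistry variables, and partial
    least squares discriminant analysis with double cross-validation,
    jack-knife variable elimination and permutation testing for urine and
    plasma LC-MS feature tables. Ships a seeded synthetic-cohort generator
    emulating the study design, preprocessing rules (category merging,
    uniform binning, presence filtering, zero replacement, scaling, pooled-QC
    screening), and annotation helpers such as acylcarnitine neutral-loss
    flagging.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
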