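Package: csfpa
Title: Pre-Analytical Effects on the Cerebrospinal Fluid Proteome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and classifies the impact of pre-analytical factors on
    cerebrospinal fluid (CSF) proteomics: blood contamination during lumbar
    puncture, the rostro-caudal concentration gradient of plasma-derived
    proteins, centrifugation before freezing, and the plasma/CSF abundance
    ratio shaped by the blood-CNS barrier. Provides reference-ratio
    quantification, fold-change and R-squared based protein categorisation
    (affected/uncertain/unaffected), cross-experiment category merging, a
    mechanistic blood-contamination forward and inverse model, collected-volume
    predictions under a linear gradient, plasma/CSF ratio statistics on equal-
    protein and equal-volume bases, and a ground-truthed synthetic-data
    generator emulating spike-in, gradient, centrifugation and paired-fluid
    study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    yaml,
    generics,
    ggplot2
Suggests:
    readxl,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
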