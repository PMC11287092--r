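Package: aesidetect
Title: Rules-Based Computable Phenotypes for Adverse Events of Special
    Interest in EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects five adverse events of special interest (AESIs) --
    myocarditis/pericarditis, anaphylaxis, Guillain-Barre syndrome,
    thrombosis with thrombocytopenia syndrome, and febrile seizure -- in
    EHR-shaped longitudinal data using a rules-based, interoperable
    computable-phenotype algorithm (final/discharge index diagnosis, care
    setting filter, clean window, condition window, supporting evidence,
    optional vaccine-exposure rule).  Ships the phenotype definitions and
    their sensitivity-analysis variants as data, a seeded synthetic EHR
    generator with ground-truth labels, and the validation machinery used
    to assess such algorithms: stratified sampling with negative controls,
    two-reviewer adjudication with a tiebreaker, dual-denominator positive
    predictive value with Agresti-Coull intervals, Cohen kappa, and a
    pooled two-sample proportion test.  Reads and writes a documented CSV
    bundle dialect and FHIR-style NDJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
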