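Package: pftminer
Title: Rule-Based Extraction of Spirometry Results from Semi-Structured
    Clinical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A facility-aware text-mining pipeline for pulmonary function
    test (PFT) reports embedded in electronic health record notes. Selects
    PFT procedures by CPT code, links candidate notes by a date window,
    screens facilities by FEV1-note coverage, cuts fixed-size character
    snippets around facility-specific anchor phrases, applies per-facility
    regular-expression dialects to extract pre-bronchodilator FEV1,
    FEV1 percent predicted, FEV1:FVC ratio and qualitative descriptors,
    classifies airflow obstruction (fixed 0.7 ratio threshold) and FEV1
    impairment severity (ATS/ERS 2005 bands), and validates output against
    adjudicated truth. Includes a seedable synthetic multi-facility note
    corpus generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    stringi,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
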