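Package: ibdclaims
Title: Administrative-Claims Case Ascertainment and Incidence Trends for
    Inflammatory Bowel Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for estimating the incidence of inflammatory
    bowel disease (IBD) from administrative health databases: a scored
    case-ascertainment algorithm that classifies patients into Crohn's
    disease, ulcerative colitis and undifferentiated IBD from ICD-coded
    physician claims and hospital discharge abstracts; incident-case
    identification with a pre-study washout period; direct age-standardized
    incidence rates per 100,000; and Poisson log-linear trend regression with
    calendar year as a categorical factor. Includes a synthetic-claims
    generator with known ground truth so every stage is testable without
    access to confidential health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
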