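Package: fracturepathways
Title: Post-Fracture Management Patterns from Administrative Claims
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A claims-based pipeline for describing medical management and
    osteoporosis-medication treatment patterns after a nontraumatic fracture
    in women aged 50 and older. Implements nontraumatic fracture
    ascertainment from diagnosis and procedure codes (with an
    inpatient/outpatient split and a site hierarchy for same-day events),
    cohort eligibility and attrition, one-year pre-index baseline profiling
    including the Charlson comorbidity index, six-month medical management
    measures (index hospitalization and length of stay, 30-day readmission,
    DXA, orthopedic surgery, rehabilitation, skilled nursing facility and
    durable medical equipment use), gap-based medication persistence
    (discontinuation after a >60-day refill gap, re-initiation, months on
    treatment) at 6/12/24-month landmarks, and subsequent-fracture detection
    under a new-site-or->90-day rule. A seeded label-first synthetic claims
    generator with per-member ground truth supports end-to-end recovery
    testing, including a scenario calibrated to published headline values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
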