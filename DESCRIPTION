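Package: triadminer
Title: Mining Multidisciplinary Collaboration Patterns in Chronic Care Event Logs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how physicians, nurses and dietitians collaborate in
    the periodic follow-up of type 2 diabetes patients in primary care, and how
    collaboration relates to glycaemic control. From raw encounter and HbA1c test
    records the package applies an eligibility funnel (minimum test count,
    comorbidity exclusion, protocol-adherence windows, study-window
    normalisation), builds per-patient discipline logs and discipline-level
    collaborative networks with participation, self-referral and referral
    indices, groups patients by care-trajectory similarity using normalised edit
    distance and agglomerative clustering, classifies clusters into seven
    collaboration patterns, segments patients by HbA1c evolution, and compares
    pattern subpopulations against the whole cohort with proportion and Fisher
    tests. A synthetic electronic-clinical-record generator with planted
    collaboration patterns, outcome trajectories and adherence violations makes
    every stage testable without access to real patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
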