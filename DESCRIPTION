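Package: wardflow
Title: Interval Census and Nurse Staffing Analytics for Hospital Ward Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of nursing care supply and demand
    from routinely collected hospital event logs. Links a nurse staffing event
    source with medical discharge data through a documented exclusion funnel,
    expands patient stays and nurse shift segments onto a unit-by-day 30-minute
    slot lattice to obtain interval censuses of patients and nurses, derives
    patient-to-nurse ratio series with median-based extreme-mismatch thresholds,
    and computes census-normalized patient turnover profiles. A discrete-event
    ward simulator generates staffing sheets and discharge records with known
    ground truth so every stage of the pipeline can be validated without access
    to real hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    arrow,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
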