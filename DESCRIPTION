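Package: drsim
Title: Agent-Based Microsimulation of Diabetic Retinopathy Progression
Version: 0.1.0
Authors@R:
    person("VA Cohort Simulation", "Maintainers", email = "drsim@example.org",
           role = c("aut", "cre"))
Description: Seeded, reproducible agent-based microsimulation of diabetic
    retinopathy (DR) progression in a clinic cohort. Generates synthetic
    patient cohorts from published summary statistics (moment-parameterized
    truncated distributions and comorbidity prevalences), assigns initial DR
    stage from logistic predicted probabilities with a prevalence-calibrated
    intercept, and steps each agent through a five-state statechart
    (no retinopathy, non-proliferative DR, proliferative DR, vision loss,
    death) with logistic and constant annual hazards plus age- and
    sex-specific life-table mortality. Includes a logistic-regression
    parameter-recovery harness, a cohort validation battery (summary t and
    chi-square tests), CSV/JSON/YAML input-output, and command-line entry
    points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
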