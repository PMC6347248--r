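Package: adcohort
Title: Cohort Projection of Alzheimer's Disease Burden and Care Costs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic age-cohort simulation of Alzheimer's disease
    progression and care costs over a long demographic horizon. Disease
    progression is a four-state absorbing Markov chain (Mild, Moderate,
    Severe, Death) whose fundamental matrix supplies expected stage
    sojourns, the limit stage mix used to seed prevalent patients, and a
    solver that converts a desired sojourn prolongation into adjusted
    transition probabilities. Incidence is calibrated on a reference run
    against an exponential age-prevalence curve and frozen across
    treatment scenarios (drug introduction year, stage-specific
    prolongations, incidence-reduction scenarios). Includes a synthetic
    EU-like cohort-component population generator, a reader for Eurostat
    bulk-download TSV extracts, stage-wise cost accounting with
    scenario-versus-reference comparison reports, and stochastic
    individual-based oracles for validating the deterministic engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
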