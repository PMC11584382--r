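Package: bapt
Title: Bariatric Surgery Assessment and Prioritisation Tool
Version: 0.1.0
Authors@R:
    person("BAPT", "Maintainers", email = "bapt@example.org", role = c("aut", "cre"))
Description: Re-implementation of the Bariatric Surgery Assessment and
    Prioritisation Tool (BAPT), an additive points system for prioritising
    patients with severe obesity and poorly controlled type 2 diabetes for
    publicly funded bariatric surgery. Provides the PAPRIKA-style adaptive
    pairwise elicitation used to build the instrument (health-state
    enumeration, dominance pruning, transitively closed preference store,
    two-criterion trade-off questions), max-margin linear-programming
    derivation of level weights, the canonical scoring and eligibility rules,
    a seeded synthetic referral-cohort and 12-month outcome generator, and the
    score-stratified outcome-analysis pipeline (chi-square, one-way ANOVA,
    age/BMI cut-point comparisons, diabetes-remission rates, AQoL-4D utility
    change against the minimum important difference).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
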