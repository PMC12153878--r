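Package: ruminbal
Title: Whole-Animal Energy and Nitrogen Metabolism Pipeline for Crossover Feeding Trials
Version: 0.1.0
Authors@R:
    person("Ruminbal", "Developers", email = "ruminbal@example.org", role = c("aut", "cre"))
Description: Tools for analysing respiration-chamber feeding trials in dairy
    cattle run as 2x2 crossover designs. Converts chamber gas-concentration
    traces into daily O2 consumption and CO2/CH4 production, partitions CO2
    into fermentative and metabolic fractions, and derives substrate oxidation
    (Frayn stoichiometry), heat production (Brouwer equation), energy balance,
    apparent digestibility, nitrogen partitioning and energy/nitrogen use
    efficiency. Includes a crossover mixed-model inference stage with a
    transformation fallback ladder, Tukey-Kramer contrasts, equivalence (TOST)
    and t-test sample-size planning, and a synthetic-trial generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
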