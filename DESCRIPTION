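Package: massai
Title: Multi-Agent Simulation of Smallholder Soil Nutrient Balances Under Fertilizer Subsidy Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples an ecological nutrient-flow module (NUTMON-style transfer
    functions for deposition, mineralisation, biological nitrogen fixation,
    erosion, sedimentation, leaching and gaseous losses) with a behavioural
    module (double-hurdle adoption/intensity models for fertilizer, manure,
    legumes and conservation practices) to project multi-year trajectories of
    soil N, P, K and organic-carbon stocks, input use and crop yield across a
    smallholder landscape of household agents and 10 m plot pixels. Includes
    fertilizer-subsidy policy scenario schedules, Monte Carlo synthesis of the
    unsampled household population, replication management with deterministic
    seeding, moving-average trend analysis with empirical confidence bands and
    Bonferroni-corrected scenario comparisons, and a synthetic landscape and
    survey generator for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
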