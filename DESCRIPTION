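Package: recsim
Title: Agent-Based Simulation of Recreation-Center Class Participation and
    Body-Weight Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates daily recreation-center exercise-class participation
    and the resulting body-weight dynamics for a synthetic urban population of
    adult women distributed across eight wards, together with a place-tailored
    digital-health app intervention (awareness/download/notification adoption
    cascade, early attrition, evening class prompts and geofence
    notifications). Participation is a five-gate daily Bernoulli decision;
    weight follows a two-compartment (fat/lean) energy-balance model with a
    Forbes partition. Experiments run replicate simulations over scenario
    grids (baseline exercise probability by app-engagement level) under
    common random numbers and report population, ward-level and time-series
    summaries with replicate confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
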