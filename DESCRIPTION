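Package: copgait
Title: Center-of-Pressure Cyclogram Gait Analysis for Perturbation-Based
    Balance Training Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing instrumented-walkway gait recordings from
    perturbation-based balance training (PBT) studies. Computes
    spatiotemporal gait parameters (stride length, stride velocity, single
    support time, integrated pressure), builds center-of-pressure (COP)
    butterfly cyclograms per gait cycle, locates the cyclogram
    self-intersection point (CISP) as a symmetry index, and measures
    single-stance COP path efficiency. Reduces per-stride and per-cycle
    metrics to subject-by-trial summaries and runs the two-group by
    two-condition statistical procedure used in PBT randomized trials
    (assumption checks with a log-transform rule, two-factor mixed-design
    ANOVA, independent t / Mann-Whitney U comparison of training trials,
    and baseline descriptive tables). Includes a synthetic-data generator
    that emulates a five-trial overground perturbation protocol with a
    walker-mounted pelvic cable robot, so the full pipeline runs and can be
    validated without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
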