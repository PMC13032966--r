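Package: dpydcea
Title: Cost-Effectiveness of DPYD Genotyping Before Capecitabine
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Cohort state-transition (Markov) model for the cost-effectiveness
    of DPYD genotype-guided capecitabine dosing in metastatic breast cancer.
    Implements genotype- and dose-tier-stratified monthly transition
    probabilities, discounted cost/QALY/life-year accumulation, incremental
    cost-effectiveness ratios and net monetary benefit, deterministic
    sensitivity analysis (one-way sweeps, tornado ordering, variant-prevalence
    threshold curve), probabilistic sensitivity analysis with Beta, Gamma and
    Triangular parameter distributions, and an individual-level
    microsimulation that serves as an independent validation oracle for the
    cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
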