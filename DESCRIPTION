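Package: volatileRL
Title: Reinforcement Learning Under Stable and Volatile Reward Contingencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-group pharmaco-EEG
    studies of probabilistic associative learning under stable and volatile
    choice-outcome contingencies. Provides the task schedule generator
    (stable 75/25 and volatile 80/20 blocks with periodic reversals),
    trial-by-trial reinforcement-learning observation models (dual
    learning-rate reward-punishment, Rescorla-Wagner delta, and
    experience-weighted attraction), hierarchical Bayesian estimation by
    MCMC with split-Rhat diagnostics, PSIS-LOO model comparison and
    posterior predictive checks, ERP peak-feature extraction (ERN, FRN,
    P300, and contralateral-minus-ipsilateral N2pc), mixed-design group
    statistics with partial eta squared and the Fisher z test for
    comparing independent correlations, and a synthetic-cohort generator
    that emulates the full study structure for power and calibration
    checks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
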