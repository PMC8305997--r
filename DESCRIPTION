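Package: dsboost
Title: Evidential Classification with Boosted Decision Stumps
Version: 1.0.0
Authors@R: person("dsboost", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Uncertainty-aware multiclass classification in the
    Dempster-Shafer framework. Basic probability assignments (BPAs) are
    derived from one-vs-one AdaBoost decision-stump ensembles trained on
    every pair of attributes: the weighted stump vote for a class pair
    yields singleton masses, a recursive area-ratio rule over the
    intersection lattice of per-class bounding boxes reallocates mass to
    composite propositions for samples in ambiguous regions, and the
    per-pair mass functions are fused with Dempster's rule of combination.
    Includes mass-function algebra with conflict handling, tabular I/O with
    missing-value support, a synthetic cluster generator with controllable
    class overlap, Monte-Carlo evaluation across training fractions, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
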