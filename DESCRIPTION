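Package: repleteRL
Title: Offline Reinforcement Learning for ICU Electrolyte Repletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning and evaluating electrolyte (potassium,
    magnesium, phosphate) repletion policies from intensive-care electronic
    health records. Provides a seeded synthetic ICU cohort simulator,
    cohort selection with 6-hour binning and last-observation-carried-forward
    imputation, construction of a Markov decision process over a discrete
    dose-and-route repletion catalog with a four-term penalty reward,
    fitted Q-iteration for offline policy learning, fitted-Q evaluation for
    off-policy value estimation, inverse reinforcement learning by discounted
    feature-expectation matching to estimate the reward weights driving
    observed behavior, descriptive comparisons of learned versus historical
    repletion (action frequencies, pre/post-repletion level distributions,
    per-visit trajectory overlays), and a configurable cost model comparing
    expenditures under historical and recommended repletion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    xgboost,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
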