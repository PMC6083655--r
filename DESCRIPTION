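Package: pcmc
Title: Post-Conflict Matched-Control Analysis of Social Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of post-conflict affiliation in group
    living animals using the PC-MC (post-conflict / matched-control)
    observation method. Reads and validates behavioural event logs and
    conflict records, labels PC-MC pairs as attracted, dispersed or
    neutral, computes corrected conciliatory tendencies (CCT) and
    time-rule first-affiliation distributions, derives dyadic
    relationship metrics (affiliation and aggression asymmetry indices,
    David's scores and rank distances), provides self-contained
    tie-corrected nonparametric tests with exact small-sample
    enumeration, and performs all-subsets AICc model selection with
    model averaging and relative variable importance over mixed-effect
    candidate models. A synthetic-data generator emulates a multi-pack
    focal-sampling study design with known ground truth so every stage
    of the pipeline can be exercised and checked for parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
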