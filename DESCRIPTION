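Package: netfp
Title: Single-Subject PET Pharmacokinetic Similarity Networks and Disease Fingerprinting
Version: 0.1.0
Authors@R: person("netfp", "developers", role = c("aut", "cre"),
    email = "netfp@example.org")
Description: Builds single-subject inter-regional pharmacokinetic similarity
    matrices from dynamic TSPO PET regional time-activity curves (standardized
    uptake values at fixed time points plus the blood-to-brain influx rate K1
    from an irreversible one-tissue compartment model), harmonizes network
    edges for technical and biological covariates with edgewise linear models,
    and runs reliability (test-retest ICC, identification), covariate and
    disease classification (L1-regularized logistic regression with regional
    importance scores), and individual-level diagnostic fingerprinting
    analyses. Includes a synthetic multi-site dynamic-PET cohort simulator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
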