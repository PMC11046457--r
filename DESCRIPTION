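Package: MVSATriage
Title: Sample-Influence Hit Triage for High-Throughput Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Hit-triage toolkit for high-throughput screening (HTS)
    campaigns built around MVS-A, a per-sample influence score accumulated
    from the gradients and hessians of a gradient-boosting classifier over
    its training iterations. High-influence primary hits persistently
    contradict the learned activity pattern and are flagged as likely assay
    false positives; low-influence hits are prioritized as likely true
    actives; high-influence primary inactives are mined as false-negative
    candidates. Includes screening-table input/output with confirmatory-
    outcome labeling and benchmark-eligibility rules, circular-fingerprint
    and physicochemical featurization with Bemis-Murcko scaffold
    extraction, primary-readout / random / isolation-forest baseline
    rankings, an early-recognition metric suite (top-K precision,
    enrichment factor, BEDROC, scaffold diversity, paired signed-rank
    significance), and a synthetic primary/confirmatory screen generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Matrix,
    xgboost,
    ChemmineR,
    ChemmineOB,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Cheminformatics, Classification, Software
RoxygenNote: 7.3.3
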