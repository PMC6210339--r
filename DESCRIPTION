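Package: cavr
Title: Dictionary-of-Motions Classification for Complex Human Activities with Variations
Version: 0.1.0
Authors@R:
    person("cavr", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Classifies complex, heterogeneous human activities recorded as
    quaternion body-pose time series. Activities are broken into short reusable
    motions by multi-scale sliding-window segmentation; per-activity k-means
    clustering with pruning and overlap resolution yields a global motion
    dictionary; each training example is represented by a tf-idf-weighted motion
    histogram (with a stop list) and a smoothed first-order transition matrix,
    and observations are classified by the lowest histogram-distance over
    sequence-probability cost. Also provides dataset-profiling Complexity and
    Variation metrics, leave-one-out and subject-holdout evaluation protocols,
    a deterministic synthetic pose-data generator with planted motion
    primitives, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
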