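Package: mantaFS
Title: Wrapper Feature Selection with Binary PSO and Manta-Ray Foraging
    Learning
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Wrapper feature selection for high-dimensional, small-sample
    classification problems such as gene-expression tumor data. Implements
    binary particle swarm optimization augmented with three manta-ray
    foraging learning strategies (chain, cyclone and somersault learning),
    a V-shaped transfer function, and a k-nearest-neighbor wrapper fitness
    that trades classification error against subset size. Includes classic
    S-shaped and V-shaped binary PSO baselines, a synthetic generator for
    high-dimensional datasets with known informative features, a
    repeated-run benchmark harness with Friedman average ranks and Wilcoxon
    signed-rank tests, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
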