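Package: dolhgs
Title: Dynamic-Opposite Hunger Games Search for Wrapper Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for high-dimensional embedding data
    (e.g. image embeddings from dermoscopy classifiers) built around a
    hybrid metaheuristic: Hunger Games Search whose per-agent updates
    compete with Particle Swarm Optimization moves, diversified by
    dynamic-opposite learning at initialization and as a per-iteration
    jumping step. Candidate feature subsets are scored by a k-nearest
    neighbour wrapper fitness balancing classification error against
    subset size. Includes standalone Hunger Games Search and Particle
    Swarm Optimization baselines, a random-subset baseline, exhaustive
    small-dimension subset search for validation, evaluation metrics
    (accuracy, precision, recall, F1, performance improvement rate,
    Friedman mean ranks), a class-conditional synthetic embedding
    generator, CSV/JSON input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
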