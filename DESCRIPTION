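Package: fragopt
Title: Fragment-Based Multi-Objective Lead Optimization over Adaptive
    Similarity-Tree Search Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Optimizes lead molecules against multiple property objectives
    while staying structurally similar to the lead. Each lead gets its own
    fragment search space: reference molecules are decomposed at exocyclic
    single bonds into attachment-marked fragments, organized in a binary
    similarity tree whose root-to-leaf paths give every fragment a short
    binary code. Molecules are embedded as concatenated fragment codes and
    evolved with a scheduled pair of bit-flip mutation operators under
    elitist Pareto selection with crowding distance; molecules passing
    decaying quality thresholds seed a pluggable generator that expands the
    search space during the run. Chemistry primitives (SMILES handling,
    fragmentation, reassembly, maximum-common-substructure and fingerprint
    similarity, property scoring) are delegated to RDKit through a
    persistent Python worker.
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
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.9) with RDKit, reachable as 'python' on
    the PATH.
Config/testthat/edition: 3
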