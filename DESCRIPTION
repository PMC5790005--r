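Package: netscreen
Title: Signed-Network Propagation Models and In-Silico Drug-Combination Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds condition-specific signed protein networks from curated
    seed proteins, converts them into trainable signal-propagation models
    constrained by a truth table of perturbation restrictions, screens all
    binary drug combinations for predicted efficacy, adverse liability and
    synergy, applies threshold- and eligibility-based candidate selection,
    and extracts mode-of-action nodes. Includes a fully seeded synthetic-data
    generator with planted synergistic drug pairs so the whole pipeline can
    be exercised and benchmarked without proprietary interactome or
    proteomic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
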