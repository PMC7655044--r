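Package: altcascade
Title: Activation Cascade Analysis of Brain Connectomes with the
    Asynchronous Linear Threshold Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Event-driven simulation of the asynchronous linear threshold
    (ALT) diffusion model on directed weighted spatial connectomes, with
    extraction of causal activation-cascade DAGs, exact path counting and
    path centrality, greedy tau-core ("hourglass waist") identification,
    degree- and attribute-preserving connectome randomizations, and
    comparison of model activation orderings against frame-quantized
    voltage-sensitive-dye imaging data. Includes seeded generators for
    connectome fixtures with mouse-cortex-like summary statistics,
    planted-hourglass networks, and synthetic VSD image stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    ape,
    jsonlite,
    yaml,
    withr,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
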