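Package: tcnet
Title: Adaptive Temporal-Causal Network Simulation with a Religion-Empathy Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for adaptive temporal-causal networks: states evolve by
    speed-factored Euler difference equations driven by an advanced logistic
    sum combination of weighted causal impacts, while designated connections
    adapt by simultaneity-based Hebbian learning with extinction. Ships a
    declarative YAML network format, a canonical 54-state cognitive-affective
    model of how an individual's God-image shapes empathic and dis-empathic
    behaviour (mirroring, as-if body loop, ownership states, goal dynamics),
    six published scenario profiles, trajectory feature extraction (onsets,
    peaks, equilibria, mirror symmetry), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
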