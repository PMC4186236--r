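Package: dacsim
Title: Distributed Adaptive Control Agent Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded, testable simulator of a layered embodied cognitive
    architecture in the Distributed Adaptive Control (DAC) tradition. A point
    agent in a continuous 2D arena is driven by three coupled control layers:
    a reactive layer of homeostatic behaviour systems performing gradient
    ascent on affordance fields under allostatic prioritization; an adaptive
    layer that learns perceptual prototypes and delta-rule valence
    associations (classical conditioning) and shapes conditioned responses;
    and a contextual layer that acquires segment sequences in short-term
    memory, consolidates them to long-term memory gated by an agency check,
    and selects actions by a four-factor rule combining perceptual evidence,
    memory chaining, goal distance and outcome valence. Protocol runners
    reproduce classic behavioural signatures: acquisition and extinction
    curves, outcome-devaluation sensitivity and its loss under
    contextual-layer lesion, recovery from kidnapping during foraging, maze
    navigation with distracters, and the robustness advantage of allocentric
    over egocentric action encoding under motor noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
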