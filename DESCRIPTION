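Package: scenegate
Title: Scene-Gated Object-Value Learning in the Striatum Tail
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a basal-ganglia circuit model in
    which medium spiny neurons (MSNs) in the tail of the striatum learn
    environment-dependent object values under scene-selective inhibition from
    fast-spiking interneurons (FSIs). Provides the delta-rule plasticity model and
    its disinhibitory choice readout, generators for scene-based and no-scene
    object-value tasks, passive-viewing schedules and synthetic single-unit
    recordings, virtual experiments reproducing the blockade, retention and
    no-scene manipulations, and electrophysiology utilities (waveform
    classification, peristimulus spike-density estimation, responsiveness tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
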