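Package: neuropong
Title: Closed-Loop Simulation of a Neural Culture Embodied in Pong
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale simulator of a closed-loop multielectrode-array
    (MEA) embodiment system in which a cultured neural network plays the
    arcade game Pong. The package couples a tick-based Pong world to a
    configurable virtual spiking culture through defined sensory-coding
    (place and rate codes over eight stimulation sites), spike-detection
    (Bessel IIR filter chain with adaptive proportional thresholding and
    stimulation blinding), and motor-decoding (region spike counts with
    activity-gain normalization) stages. It also provides the bespoke
    analysis statistics used to characterise such systems - gameplay rally
    metrics, clustered binary information entropy of spike rasters,
    centre-of-activity functional plasticity, spatial DCT asymmetry modes,
    lagged cross-correlation connectivity, exclusive motor events - and an
    EXP3 adversarial bandit for online selection of motor-electrode layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
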