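Package: rampulse
Title: Charge-Balanced Cochlear-Implant Pulse Shapes and Cortical Growth-Function Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Synthesis of charge-balanced biphasic cochlear-implant pulse
    waveforms (rectangular, fixed-slope and fixed-amplitude ramped families,
    cathodic- or anodic-first) across a uniform charge schedule, including
    device current-step quantization; quantification of auditory-cortex
    growth functions from multi-unit spike-event tables (threshold with a
    three-standard-deviation criterion and consecutive-level confirmation,
    maximal evoked firing rate, charge at maximum, dynamic range and its
    80-percent variant); paired Wilcoxon signed-rank comparison of ramped
    versus rectangular shapes; and a calibrated Poisson multi-unit spike
    simulator providing ground truth for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
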