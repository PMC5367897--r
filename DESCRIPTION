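Package: tonecloud
Title: Tone-Cloud Textures and Statistical Change-Detection Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis of stochastic tone-cloud acoustic textures whose
    statistics change mid-trial, together with two observer models of
    statistical change detection (a dual-timescale leaky estimator of
    per-channel tone probability, and a simplified auditory-cortex
    modulation-filterbank model with a collapsing decision bound) and the
    signal-detection analyses used to quantify detection behaviour:
    time-resolved d-prime, instantaneous false-alarm hazard, Erlang-CDF
    performance dynamics, and reaction-time AUROC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
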