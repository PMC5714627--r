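Package: surro4dct
Title: Dual External-Surrogate Waveform and 4D CT Sorting Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing two synchronized external respiratory
    surrogates (an infrared marker-block channel and a pneumatic bellows
    channel) in the context of retrospective phase-based 4D CT sorting.
    Reads the two trace dialects, synchronizes waveforms at the X-RAY ON
    origin, resamples, normalizes, detects end-inhale peaks (including
    plateau midpoints), and summarizes inter-surrogate latency,
    amplitude variability and correlation. Assigns continuous
    respiratory phase from end-inhale tags, sorts oversampled helical
    slices into ten phase volumes, builds maximum intensity projections,
    and quantifies segmentation agreement (Dice, overlap index, volume
    and centroid change, differences from a ground-truth internal target
    volume). Includes a programmable digital moving phantom and
    dual-surrogate signal generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
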