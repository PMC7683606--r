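Package: surgewave
Title: Ultradian Wavelet Power of Wearable Physiology for LH Surge Anticipation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for anticipating the preovulatory luteinizing hormone (LH)
    surge from wearable physiological time series. Implements a synthetic
    cohort generator for distal body temperature, sleeping heart rate and
    heart rate variability with a latent ultradian amplitude envelope;
    ingestion and cleaning of per-cycle wearable exports; a generalized
    Morse wavelet continuous transform with 2-5 h ultradian and 23-25 h
    circadian band-power extraction; detection of the stereotyped
    inflection, peak and post-surge trough features of ultradian power
    relative to LH surge onset; cycle inclusion and perimenopausal
    classification rules; and the rank-based and repeated-measures
    statistical comparisons used to evaluate the features at cohort level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
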