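Package: vowelmarker
Title: Acoustic Marker Screening and Clinical Validation from Sustained Vowels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for screening and validating vowel-acoustic biomarkers of
    tongue-related articulation disorders. Synthesizes sustained corner-vowel audio
    with controlled formant centralization, extracts F1/F2 by linear-prediction
    analysis of a steady 200-ms segment, derives the formant centralization ratio
    (FCR), vowel space area and related distinctive-feature metrics, ranks markers by
    per-syllable gender-stratified linear support-vector-machine weights, and
    validates the selected marker with questionnaire reliability, stage-trend
    regression, mixed-effects pre/post models and ROC cutoff analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    lme4,
    lmerTest,
    emmeans,
    car
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
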