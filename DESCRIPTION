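Package: rfqus
Title: Quantitative Ultrasound RF Spectral Features and Lymph Node
    Metastasis Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates pulse-echo radio-frequency (RF) ultrasound frames from
    scatterer phantoms, computes the eight quantitative backscatter spectral
    parameters of a region of interest (Higuchi fractal dimension, spectral
    slope, intercept, mid-band value, and the four sub-band mean powers
    S1-S4), and runs the full statistical cascade used to associate these
    features and TI-RADS sonographic codes with cervical lymph node metastasis
    in papillary thyroid carcinoma: group-wise pooled t and Pearson chi-square
    tests, fixed-orientation ROC analysis with tie-corrected AUC and
    Hanley-McNeil confidence intervals, and standardized-coefficient linear
    regression. Includes a two-group cohort simulator parameterized by the
    published study summaries, so the pipeline is exercisable end to end
    without patient data, and a binary RF frame container with a JSON
    metadata sidecar.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
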