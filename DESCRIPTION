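Package: sertgain
Title: Separable Gain Analysis of Ongoing and Evoked Cortical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for trial-based optogenetic experiments that
    probe serotonergic gain control of population activity in mouse primary
    visual cortex. Provides preprocessing of wide-field calcium trial movies
    (delta-F/F, ICA-based artifact rejection, spatial Gaussian and Butterworth
    filtering, ROI extraction), decomposition of photostimulated activity into
    spontaneous and evoked components, classification of suppression as
    divisive versus subtractive by linear regression on pre/post firing rates,
    Naka-Rushton contrast-response fitting with max-normalization tests, a
    linear gain decomposition of control responses into weighted evoked and
    baseline components, and one-sided t tests with max-statistic sign-flip
    permutation correction. A synthetic-data module generates trial movies and
    multi-unit spike counts with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    minpack.lm,
    ica,
    signal,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
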