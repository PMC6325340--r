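Package: benthosurvey
Title: Simulation and Analysis of Image-Based Abyssal Megafauna Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning and analysing photographic surveys of abyssal
    megabenthos, built around a virtual-ecologist simulator of AUV
    photo-transects over polymetallic-nodule landscapes. Generates synthetic
    horst-and-graben bathymetry, nodule-cover random fields and long-tailed
    megafauna communities; classifies landscape types from bathymetric
    position index and terrain ruggedness; computes environmental descriptors
    (nodule cover, grain-size statistics, carbonate and C:N), standing-stock
    and Hill-number diversity metrics, sample-based rarefaction and
    extrapolation, and K-dominance curves; runs Bray-Curtis composition
    analyses (nMDS, PERMANOVA with pairwise follow-ups, SIMPER, Spearman
    correlations) implemented from first principles; and evaluates
    sampling-unit-size adequacy through bootstrap accuracy, precision and
    autosimilarity curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
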