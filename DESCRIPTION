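Package: intragro
Title: Intra-Annual Tree Growth Projection from Dendrometer Cycle Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters diurnal stem-circumference cycles recorded by band
    dendrometers with dynamic-time-warping k-means, learns a random-forest
    mapping from daily climate to cycle class, evaluates and statistically
    downscales climate-model output with the Kling-Gupta efficiency and
    random-forest regression, and projects monthly tree growth and statistical
    growing-season onset/cessation dates under future climate scenarios.
    Includes a seeded synthetic-data generator emulating monsoonal climate,
    archetypal diurnal cycles, sensor jumps and gaps, so the whole pipeline is
    testable without field data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    mgcv,
    ranger,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
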