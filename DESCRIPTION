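Package: grainmix
Title: Gaussian Mixture Modelling of Individual Grain-Weight Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the distribution of individual cereal grain
    weights as finite mixtures of normal distributions. Provides univariate
    Gaussian-mixture fitting by expectation-maximisation with deterministic
    restarts, AIC/AICc/BIC selection of the number of components, the
    preprocessing stages common in grain phenotyping studies (heaviest-head
    selection, interquartile-range outlier removal, min-max scaling,
    Shapiro-Wilk normality checks), a synthetic-data generator emulating a
    cultivar x seeding-rate x sampling-time study design, and an end-to-end
    analysis pipeline with deterministic CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
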