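Package: deepdreamr
Title: Deep-Dream Video Synthesis with Temporal Coherence and
    Altered-States Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for generating simulated visual hallucinations in
    images and video by multi-octave gradient ascent against a clamped
    layer of a convolutional network (Deep Dream), with an optical-flow
    based temporal-coherence stage that warps and blends hallucinatory
    content from frame to frame, including equirectangular (panoramic)
    seam handling. Ships a deterministic toy convolutional network and
    synthetic-data generators (moving-texture video with ground-truth
    flow, two-condition questionnaire ratings, scalar-timing temporal
    production) so the whole pipeline is testable offline. Also provides
    the statistical machinery used in altered-states-of-consciousness
    experiments: Jeffreys-Zellner-Siow (JZS) default Bayes-factor t-tests
    with a Cauchy prior on the standardized effect, Cohen's d from t
    statistics, Bonferroni correction, Bayes-factor interpretation
    thresholds, and classical two-way repeated-measures ANOVA with
    screening rules for temporal-production data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
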