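Package: abneuro
Title: Quantitative Analysis of Adult-Born Juxtaglomerular Neuron Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal in vivo studies of adult-born
    olfactory-bulb juxtaglomerular neurons. Computes ratiometric (FRET)
    calcium-trace features and classifies cells by spontaneous calcium
    fluctuations (mid-reference crossing counts clustered with a Gaussian
    mixture model under BIC selection), detects odor-evoked transients,
    quantifies 3-D saltatory migration, dendritic morphometry (total dendritic
    branch length, branch counts, Sholl profiles), longitudinal cell survival
    by tolerance-gated optimal position matching, normalized
    immunofluorescence levels, patch-clamp estimators (action-potential
    threshold, input resistance, resting membrane potential), and
    counts-per-million expression filtering with fold-change classification of
    differentially expressed genes. A synthetic-data generator with known
    ground truth makes every stage verifiable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    igraph,
    mclust,
    pracma,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
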