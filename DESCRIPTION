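Package: peernet
Title: Patient-Sharing Physician Networks and Peer Effects on Trial Participation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing within- and between-hospital physician
    social networks from patient billing records and modelling peer effects
    on physician participation in clinical trials. Builds weighted and
    binarized shared-patient networks, computes network metrics (degree,
    betweenness centrality, density, per-hospital subnetwork density) and
    the Shannon diversity of a physician's hospital billing shares, derives
    step-masked within- and across-hospital peer-participation exposures
    for stepped-wedge designs, and fits fixed- and random-intercept
    logistic regression models of participation with manual model
    reduction. Includes a synthetic billing-data generator with a
    sequential adoption process and known coefficients, plus parameter
    recovery experiments, so the full pipeline is exercisable without
    restricted billing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
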