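Package: wakamola
Title: Chatbot-Style Health Assessment Scoring, Social Networks and Cohort Simulation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for population screening of overweight and obesity risk
    with a conversational questionnaire. Implements the Wakamola assessment:
    food-frequency diet scoring against a healthy-eating penalty table,
    physical-activity scoring from IPAQ short-form MET-minutes, a five-level
    BMI point score, a social-network score propagated over typed contact
    graphs by fixed-point iteration, and the composite Wakastatus on a 0-100
    scale. Includes typed relation-graph construction with Louvain community
    detection and colour-coded exports, a synthetic-cohort simulator
    calibrated to a published university pilot, a transport-agnostic
    multilanguage dialogue engine, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
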