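Package: autocmap
Title: Auto-Contractive Maps and Semantic Connectivity Maps for Marker
    Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers many-to-many association networks among bounded
    quantitative variables with an Auto-Contractive Map (AutoCM), an
    unsupervised neural network whose trained connection weights are read
    directly as association strengths.  Provides complement ("high"/"low")
    min-max preprocessing for marker panels, deterministic AutoCM training,
    conversion of weights to distances and link strengths, minimum
    spanning tree filtering into a semantic connectivity map with hub
    scores, graph export (GraphML, DOT, TSV), and a configurable synthetic
    multiple-sclerosis cohort generator for end-to-end validation of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
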