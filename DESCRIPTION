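Package: oligoexo
Title: Quantitative Analysis of pHluorin-Reported Exocytosis in
    Oligodendrocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection and classification of exocytotic events in
    pHluorin time-lapse fluorescence movies of oligodendrocytes, together
    with the downstream quantitative models used to interpret them.
    Includes photobleaching correction and dF/F normalisation, detection
    of Gaussian-shaped fusion puncta by a baseline-standard-deviation
    criterion, classification of full-vesicle fusion versus kiss-and-run
    by the border decay ratio of fluorescence half-lives, spatial
    statistics of events within myelin sheaths (paranodal versus
    internodal), node-of-Ranvier classification from dual-channel line
    scans, the N*L*I myelin-coverage model, and a spherical-vesicle
    membrane budget. A seeded synthetic-imaging module generates
    ground-truthed time-lapse stacks, sheath event layouts and node
    profiles so that every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
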