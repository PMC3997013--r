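Package: peristalmap
Title: Spatiotemporal Mapping and Neurogenic State Analysis of Gut Peristalsis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts silhouette video and multichannel intraluminal manometry
    of ex vivo tubular gut preparations into aligned spatiotemporal maps of
    diameter and pressure, classifies every point in space-time into one of
    twelve mechanical muscle states via a hidden Markov trend decoder built on
    a Gaussian quiescence model, separates neurogenic from myogenic activity
    with an orbit-path-length threshold calibrated on a nerve-blocked (TTX)
    recording, and quantifies initiation, propagation and bolus-coupling of
    peristaltic contractions. Includes a ground-truthed synthetic preparation
    generator so every stage of the pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
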