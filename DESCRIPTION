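Package: cellspan
Title: Single-Cell Replicative Lifespan and Life-History Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing replicative aging of single budding-yeast
    mother cells followed in microfluidic devices. Reads wide-format
    longitudinal tables of per-division cell size, elapsed time and
    (optionally) fluorescence-reporter intensity, smooths each cell's series
    with a cubic smoothing spline, detects the Senescence Entry Point as the
    elbow of the division-duration profile, and relates life-history
    features to replicative lifespan via per-age Pearson correlation
    screens, median-split Kaplan-Meier comparisons with the log-rank test,
    and rank-sum tests. A stochastic life-history generator with known
    ground truth reproduces the assumed data structure so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl,
    yaml,
    optparse
Config/testthat/edition: 3
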