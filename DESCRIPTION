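Package: chamberpref
Title: Preference and Activity Analysis for Choice-Chamber Detection Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the behavior of small groups of laying hens
    housed in a three-compartment environmental preference chamber from
    per-frame object-detection streams. Ingests per-compartment bounding-box
    records, computes an identity-free unrest (activity) index based on the
    symmetric Hausdorff distance between consecutive frames' detection
    centroids, estimates permanence time per light and temperature treatment
    from per-frame bird counts, and compares treatments with one-way and
    factorial ANOVA, Tukey HSD and compact letter displays. Includes
    count-level detector validation metrics (confusion matrix, accuracy,
    over-count rate, single-class average precision), a finite-population
    sample-size calculator for annotation planning, and an agent-based
    simulator of hens moving among compartments that provides ground truth
    for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
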