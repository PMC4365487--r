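Package: neuralplate
Title: Planar Polarity, Rosette Coordination and Morphometrics for Segmented Neural Plate Epithelia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantification pipeline for segmented apical surfaces of the
    mouse neural plate epithelium. Extracts a cell/junction/vertex graph from
    watertight label images, measures orientation-binned junctional
    fluorescence to score planar cell polarity, partitions fluorescence into
    junctional and medial pools, computes apical-area statistics, detects
    multicellular rosettes by ROI-expansion coordination numbers, and
    summarises embryo-level neural tube defect penetrance, axis-length ratios
    and spina bifida severity. Includes a seeded synthetic-tissue generator
    (tessellations, fluorescence channels, embryo cohorts) with full ground
    truth so every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
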