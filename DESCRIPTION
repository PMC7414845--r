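Package: paleocanid
Title: Morphometric, Microtomographic, Ancient-DNA and Radiocarbon Tools
    for Discriminating Late Pleistocene Dogs from Wolves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for the lines of evidence used to separate
    early domestic dogs from wolves in Late Glacial faunal assemblages:
    log-shape-ratio biometry of postcranial elements against a standard
    skeleton, microCT tissue analysis of the lower carnassial (percent of
    crown dentine between cervix-parallel cross-sections, occlusal wear
    screening, broken-cervix reconstruction) and of metacarpal epiphyses
    (trabecular BV/TV maturity screening), sliding-semilandmark outline
    geometric morphometrics of the first lower molar crown with
    between-group PCA and allometry testing, authenticity summaries of
    aligned ancient-DNA read sets (fragment length, terminal deamination,
    coverage), and radiocarbon combination and calibration with highest
    posterior density ranges. A seeded synthetic-data module generates
    tooth and epiphysis voxel phantoms, outline populations, osteometric
    tables, damaged read sets and calibration curves with known ground
    truth so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    Rcpp,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
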