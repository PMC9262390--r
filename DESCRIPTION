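Package: spindlepol
Title: Quantification of Planar-Polarized Spindle Orientation and Cortical
    Polarity in Epithelial Mitotic Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify planar cell polarity of cortical proteins and
    mitotic spindle orientation in epithelial mitotic domains. Extracts and
    normalizes cortical intensity profiles along traced cell perimeters,
    computes the peak-to-trough polarity ratio and the angle of maximum
    cortical intensity, measures signed and folded division angles and spindle
    rotation from time-lapse stacks, fits moment-equivalent ellipses to cell
    contours to test the long-axis (Hertwig) rule, and performs the exact
    two-sample Mann-Whitney and Spearman correlation inference used for
    small per-embryo samples. A synthetic mitotic-domain generator produces
    multi-channel image rasters and spindle time-lapses with known ground
    truth for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
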