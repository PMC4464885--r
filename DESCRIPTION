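Package: fretscreen
Title: Bacterial Colony Screening of FRET Biosensor Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of wide-field bacterial colony screens
    for ratiometric FRET biosensors. Generates ground-truthed synthetic
    three-channel plate image stacks (colony layout, spray-deposition
    heterogeneity, response kinetics, photon shot noise), identifies
    colonies by thresholding and morphological cleaning, extracts
    per-colony FRET ratio time series, computes basal ratios and relative
    ratio changes, ranks colonies by a brightness-biased response score,
    selects top performers for picking, and quantifies spatial bias and
    plate-to-reference agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    EBImage,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
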