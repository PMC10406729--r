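Package: peakfinger
Title: Structure Annotation from 2D HSQC NMR Spectra via Multi-Task
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for NMR-based dereplication of small molecules. Parses
    1H-13C HSQC peak lists, rasterizes them to fixed-geometry images, and
    trains a multi-task convolutional network that predicts a 6144-bit
    Morgan-style chemical fingerprint, molecular weight, compound class,
    and glycoside status directly from the spectrum. Predicted fingerprints
    are scored against a reference library by cosine similarity to rank
    candidate structures, with identification/annotation rates and
    precision/recall at k for benchmarking, a chemical-shift tolerance
    matcher as a baseline, occlusion-sensitivity attribution that maps
    HSQC peaks onto atoms of a candidate structure, and a synthetic
    HSQC simulator for building fully reproducible training sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
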