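Package: gridedit
Title: Simulation and Quantification of Arrayed CRISPR Editing Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for arrayed CRISPR-Cas9 editing experiments on
    micropatterned culture plates. Designs one-pot sgRNA transcription
    primers and paired-guide genomic deletions; simulates the inputs such
    an experiment produces (per-microfeature fluorescence time-lapse
    images with ground-truth cell counts, amplicon sequencing reads with
    ground-truth edits, genotyping-gel band tables); quantifies them by
    illumination correction, nuclei segmentation and counting,
    exponential growth-curve fitting and clone classification, amplicon
    read alignment and indel calling around the Cas9 cut site, and
    gel-based deletion genotyping; and orchestrates the whole
    simulate-count-fit-classify-pick workflow end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    MASS,
    png,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
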