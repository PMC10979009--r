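Package: nucleoidshape
Title: Quantifying the Shape of Unconfined Bacterial Chromosomes from
    Single-Cell Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for characterizing the unconfined
    bacterial chromosome in expanded (wall-less, spheroidal) Bacillus
    subtilis cells. Detects round cells from multichannel fluorescence
    stacks, screens them by roundness and by the single-ParB-focus rule,
    fits an annular "backbone" through the crescent-shaped nucleoid,
    extracts origin-anchored intensity profiles and population demographs,
    decomposes the DNA pattern into PSF-limited spots grouped into
    PSF-linked clusters, counts and pairs sub-pixel fluorescent foci
    (ori/ter ratios, inter-focus distances), classifies chromosome shapes
    into toroid/crescent/compact/other, and estimates condition-level
    shape ratios by bootstrap resampling. Ships a ground-truthed synthetic
    microscopy generator (Gaussian PSF, Poisson shot noise, Gaussian read
    noise) so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
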