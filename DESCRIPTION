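Package: fscclone
Title: Clonal Analysis of Drosophila Follicle Stem Cell Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of mitotic-recombination
    lineage tracing in the Drosophila ovariole. Implements the marker
    combinatorics of Flp/FRT clonal marking systems (single-FRT GFP-negative
    labelling, MARCM, and a dual-FRT three-colour scheme), a stochastic
    germarium and clone simulator producing per-ovariole clone inventories
    over a days-post-heat-shock time course, clone-pattern classification,
    closed-form lineage timing, inference of active follicle stem cell (FSC)
    number from clone-size fractions with bootstrap uncertainty, and a 3D
    image-based clone-size quantification pipeline (synthetic two-channel
    stacks, nucleus segmentation, automated label thresholding). All analyses
    run on synthetic data generated within the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    clue,
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
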