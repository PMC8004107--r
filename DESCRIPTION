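Package: brainfish
Title: Single-Molecule FISH Quantification in Intact Drosophila Brains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistically controlled quantification of single-molecule
    fluorescence in situ hybridization (smFISH) in whole-mount Drosophila
    brains. Provides per-voxel 3D generalized likelihood ratio test spot
    detection with Benjamini-Hochberg false discovery rate control, Poisson
    maximum-likelihood refinement of spot position, brightness and width,
    chromatic-shift correction between imaging channels, compartment masks
    from drawn polygons and a difference-of-Gaussians membrane-label
    threshold, transcription-focus characterization, bleach- and
    background-corrected fluorescent protein intensities, and skeleton/mesh
    based dendritic morphometry. A ground-truthed synthetic scene generator
    makes every stage testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
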