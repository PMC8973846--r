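Package: nucleoshape
Title: Nucleolar Morphology Scoring, 3D FISH Compartment Analysis, and
    Screen Statistics for Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative image analysis of nucleolar maturation in
    fluorescence microscopy. Classifies nucleoli as ring-like from the
    ratio of mean intensities over concentric radial layers, scores
    circularity (FormFactor) with small-object exclusion, segments nuclei
    and nucleoli in 2D snapshots and anisotropic 3D stacks, detects FISH
    foci and measures their distances to the nearest nucleolus surface
    and the nuclear border, assigns nuclear compartments, selects nascent
    transcription foci, and computes plate Z-scores and hit calls for
    siRNA screens together with the chi-squared and t-test statistics
    used to compare cell populations. Includes a ground-truthed synthetic
    scene generator for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
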