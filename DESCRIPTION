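Package: periprobe
Title: Quantification of Age- and Disease-Associated Pathology Around
    Chronically Implanted Microelectrodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying tissue responses around chronically
    implanted intracortical microelectrodes from multiphoton z-stacks and
    immunostained sections. Builds anisotropic 3D Euclidean distance maps of
    the electrode surface from a rotated 2D footprint, segments autofluorescent
    lipofuscin granules by dual-channel 1:1 colocalization and methoxy-X04
    labeled amyloid deposits by a Gaussian-subtraction/bandpass/median filter
    chain with a mean + k*SD threshold, tracks plaques longitudinally via
    vasculature-based registration and centroid matching, profiles marker
    intensity and DAPI-based cell counts in concentric annuli with
    contralateral-hemisphere normalization, and applies mixed-design
    repeated-measures ANOVA with Bonferroni post-hoc tests and Welch's t-test.
    A seeded synthetic-data module generates image stacks and sections with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
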