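Package: phmri
Title: Pharmacological MRI Volume-of-Activation and Resting-State Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise analysis of pharmacological MRI (phMRI) experiments in
    the awake rodent brain. Computes BOLD percent-change maps against a
    pre-injection control window, applies a signal-change floor and a
    Benjamini-Hochberg false-discovery-rate filter to voxelwise one-sample
    t-tests, counts per-region positive and negative volumes of activation
    (VoA) against an integer-labelled atlas, and assembles group composite
    maps through inverse affine transforms with trilinear interpolation. A
    companion resting-state arm builds region-to-region Pearson/Fisher-z
    connectivity matrices, one-group Z matrices, thresholded brain graphs and
    graph-theory summaries (degree centrality, density, average path length).
    Includes a synthetic 4D data generator with planted dose-scaled
    activation and planted network structure for end-to-end validation, and
    group-level dose statistics (Kruskal-Wallis with omega-squared effect
    sizes, Welch and rank two-group tests, blocked ANOVA with Tukey post-hoc).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    signal,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
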