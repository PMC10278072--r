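Package: linkerscape
Title: Interdomain Linker Analysis for Cellobiose Dehydrogenase-Like Flavocytochromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the interdomain linker of cellobiose
    dehydrogenase (CDH) and related multidomain flavocytochromes. Implements
    a function-based linker definition anchored on the conserved cytochrome
    Tyr and the Tyr/Phe-Asp-Tyr end motif, tripartite segmentation into
    N-attached, mobile and C-attached regions, amino-acid class composition
    and length statistics, sequence-logo frequency matrices with information
    content, sequence-similarity-network grouping of linker sets, rational
    linker-variant design (deletions, Ala-Thr insertions, engineered
    disulfides) with coordinate maps and theoretical masses, post-processing
    of steered-pull trajectories (center-of-geometry distances, distortion
    cutoffs, Savitzky-Golay smoothing), and single-exponential fitting of
    stopped-flow absorbance traces. A seeded synthetic-data generator
    produces CDH-like sequence families, pull trajectories and kinetic
    traces with ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    igraph,
    signal,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
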