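Package: EmbryoSynchrony
Title: Division Synchrony Analysis of Preimplantation Embryos from 4D
    Fluorescence Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cell-division synchrony in time-lapse
    fluorescence recordings of preimplantation embryos. Detects nucleus
    centroids in anisotropic 3D image stacks (background subtraction,
    clip-limited equalization, z-bias correction, Otsu thresholding and
    iterative watershed subdivision of merged nuclei), links detections
    into blastomere lineage trees, and computes morphokinetic statistics:
    cell-count curves aligned to first mitosis, intra/inter stage
    durations, per-round division durations, the coefficient of variation
    of third- and fourth-round durations (the synchrony index),
    morphometric descriptors (distance CV, Procrustes shape distance,
    embryo motility) and outcome statistics (test-selection policy,
    two-proportion test, Spearman correlation, per-time count comparison
    and ROC cutoff analysis). Ships a synthetic embryo generator (lineage,
    confined nucleus motion, Gaussian-blob volume rendering) so the whole
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    nortest,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
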