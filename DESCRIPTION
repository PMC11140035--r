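Package: organoidKit
Title: Multimodal Mechanical and Transcriptomic Profiling of Brain Organoids
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for multimodal profiling of
    stem-cell-derived brain organoids under drug exposure. Implements a
    reverberant optical coherence elastography (Rev-OCE) pipeline from
    phase-sensitive OCT phase differences to local shear-wave-speed maps
    via windowed 2D autocorrelation wavenumber estimation; Brillouin
    spectrometer calibration against reference liquids and Lorentzian
    frequency-shift fitting with OCT-guided surface sampling; OCT-based
    segmentation and spherical volumetry; counts-per-million expression
    summarisation with fold-change thresholding, Venn partitioning and
    principal component analysis; and group statistics (one-way ANOVA with
    Bonferroni pairwise comparisons, exact binomial prevalence intervals).
    Every estimator ships with a seeded synthetic-data generator carrying
    known ground truth: isotropic reverberant shear-wave fields over
    two-compartment spherical phantoms, Lorentzian Brillouin spectra with
    pixel-to-GHz calibration, speckled OCT intensity volumes, and
    negative-binomial RNA-seq counts with planted effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    cluster,
    optparse
biocViews: Software, Transcriptomics, Normalization,
    PrincipalComponent, Visualization
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
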