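Package: ShoalVision
Title: Quantitative Analysis of Biological-Motion Shoaling, Neural Tuning
    and Whole-Brain Activity Mapping in Zebrafish
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying visual social behaviour and its neural
    correlates in larval and juvenile zebrafish. Implements virtual
    conspecific stimulus kinematics (bout-like and continuous dot motion,
    Gaussian speed-profile bouts, trefoil and circular trajectories,
    looming discs), shoaling statistics from paired tracking data
    (time-shift-null attraction, egocentric neighbour-density maps,
    radial repulsion scores, bout detection, looming escape fractions),
    calcium-trace tuning analysis (stimulus-epoched dF/F, bout preference
    index, quadratic-spline tuning peaks), per-hemisphere Gaussian kernel
    density mapping of classified neurons in reference-brain space, and
    condition-dependent immediate-early-gene quantification from
    two-channel volumes (depth normalization, bulk cluster signal,
    Cohen's d effect matrices with Bonferroni-corrected tests,
    hierarchical clustering). A synthetic-data module generates every
    input class with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    splines,
    signal,
    tiff,
    ape,
    EBImage,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
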