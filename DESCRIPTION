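Package: octanv
Title: Quantification of Retinal Neovascularization Structure and Flow in OCTA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies diabetic retinal neovascularization (NV) from optical
    coherence tomography angiography (OCTA) by combining structural and flow
    (angio) information. Implements Phansalkar auto-local thresholding and
    ROI-restricted flow-density measurement on en face maximum-intensity
    projections of the vitreoretinal-interface slab and on cross-sectional
    B-scans with red flow overlay, longitudinal endpoint selection
    (posttreatment and last follow-up relative to an initial anti-VEGF
    injection block), and nonparametric cohort statistics (median/range,
    mean with normal 95 percent confidence intervals, Wilcoxon signed-rank
    tests). A synthetic OCTA generator produces volumes with a known
    branching NV, separate reflectivity and decorrelation channels, speckle
    noise, and a treatment-response process in which flow regresses within a
    persisting structural scaffold and may recur, so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
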