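Package: dopaquant
Title: Quantification of Striatal Dopamine Release from Amperometry and
    Superresolution Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification machinery for studies of striatal dopamine
    release. Implements carbon-fiber amperometry trace metrics (electrode
    calibration, current-to-concentration conversion, stimulus-artefact
    blanking, peak amplitude, 20-80% rise time, windowed area under the
    curve, train normalization, uptake-blocker comparisons, KCl responses,
    microdialysis normalization); a 3D structured-illumination image
    pipeline for dopamine-axon and release-site quantification (Otsu
    segmentation, size filtering, axon volume fraction, skeleton-based
    axon length density, cluster overlap classification, and a
    local-shuffle null); a 2D synaptosome colocalization procedure
    (rolling-ball background subtraction, punctum detection with size and
    shape filters, category assignment, Synaptotagmin-1 positivity by an
    overlap criterion); and ground-truthed synthetic generators for
    volumes, traces, and punctum fields so every stage is testable without
    acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    jsonlite,
    pracma,
    Rcpp,
    signal,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
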