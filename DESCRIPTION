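Package: plaquefp
Title: Depth-Resolved Fiber Photometry of Amyloid Plaque Signals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for depth-resolved fiber photometry of
    amyloid-plaque tracer signals in mouse models of Alzheimer's disease.
    Covers demodulation of time-division-multiplexed photometry recordings
    from flat and tapered optical fibers, plaque particle detection in
    fluorescence section images, fiber-track reconstruction and moving-ROI
    depth profiling, autofluorescence baseline modelling and subtraction,
    photometry-versus-histology rank correlation, ex vivo photometry-stack
    simulation (collection x illumination fields), and leave-one-out
    genotype classification of depth profiles. A synthetic-data generator
    produces genotype-dependent 3-D plaque fields, section images, taper
    illumination and collection fields, and raw multiplexed recordings
    with known ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    e1071,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Software, Preprocessing, Classification, SingleChannelDetection
RoxygenNote: 7.3.3
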