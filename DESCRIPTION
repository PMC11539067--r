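Package: finwave
Title: Undulatory Swimming Kinematics, Wave Decomposition and Escape-Response
    Analysis for Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying zebrafish locomotion from high-speed video
    and tank electrophysiology. Implements a parametric kinematic model of
    body undulation as the superposition of a pectoral standing wave and a
    caudal travelling wave, a standing/travelling wave decomposition of
    tracked bending fields, and an elongated-body-theory propulsion model
    used to test whether an enlarged, caudally shifted pectoral standing wave
    can compensate for a stiffened caudal travelling wave. Also provides a
    silhouette-skeleton midline tracker, kinematic and arena-occupancy
    features (tortuosity, thrust velocity, bending angle, centre occupancy),
    Mauthner-cell field-potential processing (band-pass and notch filtering,
    spike detection, amplitude classes, instantaneous spike frequency,
    peristimulus histograms), axon cross-section morphometry with operator
    blinding, frameshift-truncation sequence utilities, and the statistics
    layer used throughout (Fisher permutation test, Benjamini-Hochberg
    correction, Wilcoxon rank-sum, bootstrap median bands). Synthetic-data
    generators with ground truth make every stage testable without external
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    signal,
    igraph,
    EBImage,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
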