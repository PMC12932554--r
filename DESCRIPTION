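Package: hycp
Title: Detection and Classification of Contraction Pulses in Hydra
    Multielectrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing extracellular multielectrode-array (MEA)
    recordings of whole small organisms such as Hydra vulgaris. Implements a
    derivative-based contraction-pulse detector (amplitude normalisation,
    moving-average smoothing, centred finite-difference first and second
    derivatives, three joint acceptance criteria with a refractory period),
    multi-recording alignment to a common comparison window, inter-peak
    interval classification into contraction pulses and inter-contraction
    burst intervals, burst segmentation, and an activity-metric suite
    including the Hydra Activity Index (contraction time over elongation
    time). A synthetic-signal simulator with ground truth makes every stage
    testable without original recordings; reporting helpers summarise
    metrics across recordings and compare experimental conditions with
    t-tests and principal component analysis. Reads and writes a documented
    HDF5 dialect and plain CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
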