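Package: CalNet
Title: Functional Network Reconstruction from Calcium Imaging and
    Multi-Electrode Array Recordings
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing directed functional networks of
    neurons and glia from fluorescence calcium recordings, and for
    characterising network bursting in multi-electrode array (MEA) spike
    trains. Calcium oscillations are detected on per-cell fluorescence
    traces by mean-plus-deviation thresholding; whole-field movies are
    segmented into spatio-temporal activity events and split into cell
    regions by watershed; pairwise coupling is quantified by the maximum
    of the lagged cross-correlation of detrended cell signals, whose
    optimal lag orients each edge; network-level statistics (connection
    count, connections per cell, signal propagation speed, mean and
    neighbour correlation, percent of maximum connectivity) summarise the
    reconstructed graphs. A synthetic-data generator plants ground-truth
    cell maps, coupled calcium transients, movies and MEA bursts so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, grDevices, graphics, S4Vectors, igraph,
    jsonlite, tiff, EBImage, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Software, CellBiology, Network, TimeCourse
RoxygenNote: 7.3.3
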