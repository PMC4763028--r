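Package: emxrt
Title: Energy-Modulated Photon Radiotherapy Planning Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale tools for energy-modulated photon radiotherapy (EMXRT)
    planning. Models percent-depth-dose curves for a 2-10 MV photon beam pool
    from benchmark water-phantom data, scores candidate energies per gantry
    angle with a four-point correlation-coefficient selector and builds the
    corresponding effective-path-length by tumor-size look-up table, traces
    rays through synthetic voxel phantoms to obtain water-equivalent path
    lengths, computes beamlet dose-deposition matrices with a divergent
    pencil-beam kernel, optimizes beamlet weights by dose-volume-constrained
    steepest descent, and evaluates plans through dose-volume histograms,
    homogeneity index, VxGy and integral dose, including paired plan
    comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
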