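Package: edbatch
Title: Batch and Real-Time Reduction of 3D Electron Diffraction Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for reducing continuous-rotation 3D electron diffraction
    (microED) data collected as many small-wedge datasets: parsing and writing
    unmerged reflection files, Laue-group symmetry machinery, per-dataset and
    merged crystallographic quality statistics (Rint, Rmeas, half-set CC1/2,
    completeness, the ISa error model, shell binning and a resolution-cutoff
    rule), unit-cell and intensity-correlation clustering of datasets,
    quality-threshold dataset selection, iterative inter-dataset scaling and
    merging with outlier-frame exclusion, detector-space geometry utilities
    (beam-centre finding, reciprocal-space mapping, rotation-axis refinement),
    a polling state machine for real-time screening and merging during
    acquisition, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
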