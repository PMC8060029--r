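Package: spikefluor
Title: Ground-Truth Calibration of Spike-to-Fluorescence Transfer in
    Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for calibrating the relationship between action
    potentials and GCaMP6 fluorescence from paired cell-attached
    electrophysiology and two-photon imaging. Includes a synthetic
    paired-recording generator with Poisson shot-noise statistics, a
    35-metric electrophysiology quality-control battery with a
    reference-range gate, isolated-event extraction and dF/F transient
    analysis, ROC-based ground-truth-optimized event detection with
    neuropil-subtraction (r) optimization, photon-gain calibration from
    the pixelwise variance-mean relation, population-imaging simulation
    by 4x spatial / 5x temporal block downsampling with DBSCAN/KS trace
    quality control, and non-negative-deconvolution spike inference with
    a binned Pearson / Matthews-correlation / event-ROC evaluation
    harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'kernel.R'
    'simulate.R'
    'artifacts.R'
    'imaging.R'
    'detection.R'
    'downsample.R'
    'ephys.R'
    'inference.R'
    'io.R'
    'photon.R'
    'qc.R'
    'spikefluor-package.R'
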