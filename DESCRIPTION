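Package: crossnobis
Title: Cross-Validated Linear Discriminant Contrast Analysis and
    Decoding-Sensitivity Simulation for Block-Design fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multivoxel pattern analysis of two-condition
    block-design fMRI experiments. Implements the cross-validated linear
    discriminant contrast (crossnobis) statistic with Ledoit-Wolf
    shrinkage-whitened discriminant weights, linear support-vector-machine
    decoding of block-wise response patterns under leave-one-subrun-out
    cross-validation, timeseries and head-motion quality-control metrics
    (temporal signal-to-noise ratio, an integrated rigid-body motion rate),
    fixed-effects permutation tests, and a calibrated generative simulation
    of block-design data with attention, thermal and spatially correlated
    physiological noise for comparing the sensitivity of the two decoding
    methods to changes in functional contrast-to-noise ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'blockDesign.R'
    'calibrate.R'
    'crossnobis-package.R'
    'detrend.R'
    'experiment.R'
    'fcnr.R'
    'glm.R'
    'io.R'
    'ldc.R'
    'ledoitwolf.R'
    'qc.R'
    'rng.R'
    'simulate.R'
    'stats.R'
    'svm.R'
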