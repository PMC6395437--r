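Package: aptwcest
Title: Quantification of Amide Proton Transfer Weighted CEST MRI with a
    Bloch-McConnell Phantom Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying amide proton transfer weighted (APTW)
    signal from chemical exchange saturation transfer (CEST) MRI of
    ischemic stroke: z-spectrum assembly from a saturated image series,
    rigid-body frame registration, voxelwise B0 inhomogeneity correction,
    magnetization-transfer-ratio asymmetry (MTRasym) mapping, lesion and
    contralateral normal-appearing white matter region-of-interest
    quantification, and time-binned treatment-response statistics
    (one-way ANOVA with least-significant-difference post-hoc tests,
    independent-samples t-tests, Pearson correlation).  A multi-pool
    Bloch-McConnell saturation-transfer simulator generates synthetic
    phantom image series and whole cohorts with known ground truth, so
    that every processing stage can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    Matrix,
    deSolve,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'aptwcest-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'bloch.R'
    'phantom.R'
    'cohort-sim.R'
    'cohort-stats.R'
    'io.R'
    'offsets.R'
    'reference-tables.R'
    'register.R'
    'roi.R'
    'show-methods.R'
    'zspec.R'
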