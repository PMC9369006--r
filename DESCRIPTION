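Package: NHfmri
Title: Network Homogeneity Mapping and Group Inference for Resting-State fMRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise network homogeneity (NH) analysis of resting-state
    fMRI networks: temporal preprocessing (motion screening, linear detrend,
    band-pass filtering, nuisance regression), simplified temporal-concatenation
    group ICA with template matching to derive a network mask, the NH statistic
    (per-voxel mean correlation with all other in-network voxels, Fisher
    r-to-z transformed and Gaussian smoothed), voxel-wise group comparison with
    covariates and Gaussian-random-field cluster-level correction, stepwise
    brain-behavior regression, and ROC / leave-one-out SVM classification.
    Includes a synthetic-cohort generator with planted regional coupling
    effects and clinical-score couplings so that every stage of the pipeline
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, RNifti, e1071
Suggests: testthat (>= 3.0.0), pROC, optparse, jsonlite, withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'volume-io.R'
    'synthetic-data.R'
    'preprocess.R'
    'network-mask.R'
    'homogeneity.R'
    'group-stats.R'
    'clinical-assoc.R'
    'classify.R'
    'pipeline.R'
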