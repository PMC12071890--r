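Package: sctselect
Title: Synthetic CT Based Photon-Proton Treatment Modality Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Expedited radiotherapy modality selection from diagnostic CT.
    Generates a planning-like synthetic CT from a diagnostic CT with a
    deformation-vector-field predicting 3D encoder-decoder network trained
    with a structural-similarity loss, preprocesses CT volumes (couch
    removal, histogram-matching HU normalization, rigid alignment,
    resampling, augmentation), computes image agreement statistics (MAE,
    universal quality index, Lin's concordance correlation), dose-volume
    histogram metric panels for thoracic organs at risk, and
    Lyman-Kutcher-Burman normal tissue complication probabilities, and
    decides the advantageous modality (photon vs proton) by the sign
    concordance of NTCP differences. Includes a thorax phantom generator
    producing paired diagnostic/planning volumes, ground-truth masks and
    deformations, and controllable photon/proton-like dose fields.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
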