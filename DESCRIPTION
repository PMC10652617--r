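Package: victa
Title: Video Cone Test Analysis for Mosquito Behaviour at Insecticide-Treated Nets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies mosquito behaviour in video-recorded WHO cone
    bioassays. Detects actively moving mosquitoes by Gaussian-mixture
    background segmentation with morphological regularisation, logs
    centroids at 0.1-s intervals, aggregates activity into 5-s epochs
    stratified by upper and lower cone regions, computes resting and
    inactivity statistics, renders minimum-intensity composite summary
    images, and merges per-assay behavioural metrics with post-exposure
    life-history records into analysis-ready tables. Includes a scripted
    synthetic-scene simulator with exact ground truth for validating every
    pipeline stage without real footage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    pracma,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
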