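Package: kneefusion
Title: Automated Knee Joint Effusion Volumetry from Paired Axial T1/T2 MRI
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated, contrast-agent-free quantification of knee joint
    effusion volume from paired axial T1-weighted and T2-trueFISP MRI volumes.
    Implements a four-stage pipeline: histogram-driven bone (femur/tibia)
    segmentation in T1 with 2D contrast correction and inter-slice repair,
    masking of non-interest structures (bones, patella, fat) in T2, recursive
    histogram thresholding of joint fluid with anatomic filtering against the
    bones, and subvoxel volumetry through a watertight triangular surface mesh.
    Includes a synthetic-data module generating calibrated cylinder/sphere
    phantoms and knee-like T1/T2 volume pairs with ground-truth labels for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
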