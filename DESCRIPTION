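Package: mr2sct
Title: Multi-Sequence MR to Synthetic CT Translation with Dosimetric QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic CT (sCT) volumes from co-registered
    multi-sequence brain MR images (T1w, T2w, FLAIR) with a conditional
    adversarial network (U-Net generator, PatchGAN discriminator), and
    evaluates the result for radiotherapy use: region-wise mean absolute
    error of the CT number, binned HU-difference profiles, median-HU
    missing-slice compensation, equivalent-path-length beam sweeps via
    exact voxel-boundary ray tracing, 2D gamma analysis, dose-volume
    histogram metrics and paired statistical comparison. Includes a
    seeded digital head-phantom generator (label maps, HU volumes,
    multi-sequence MR with Rician noise and bias fields, analytic dose
    grids) so the whole pipeline runs end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
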