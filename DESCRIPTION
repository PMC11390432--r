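Package: perivox
Title: Multi-Scale Supervised Dense Nested Segmentation of Perivascular
    Spaces on T2-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Segmentation and quantification of perivascular spaces (PVS,
    Virchow-Robin spaces) on axial T2-weighted 3T magnetic resonance
    volumes.  Implements a densely nested encoder-decoder network with
    per-depth output heads, foreground-preserving multi-scale label
    pyramids for deep supervision, and a soft-dice loss, trained with
    Adagrad under an age-balanced five-fold cross-validation protocol.
    Includes voxel-level evaluation (Dice similarity coefficient,
    sensitivity, positive predictive value), slice-based PVS counting on
    anatomically selected basal-ganglia and centrum-semiovale slices with
    Spearman rank agreement against rater counts, and a synthetic phantom
    generator producing brain-like volumes with tubular and dot-like
    CSF-bright structures, sulcus- and lacune-like confounders, and
    ground-truth masks so the whole pipeline is testable without patient
    data.
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
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
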