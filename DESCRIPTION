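Package: menisci
Title: Quantifying Meniscal Motion in Loaded-Knee MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures in vivo motion of the medial and lateral meniscus
    between unloaded and varus/valgus-loaded 3D knee MRI. Scans are first
    aligned by a rigid registration restricted to the tibial bone mask, then a
    dense meniscal deformation field is estimated by a variational nonlinear
    registration combining a masked sum-of-squared-differences similarity, a
    curvature regulariser and a surface-distance penalty computed from a
    distance transform of the meniscus contours, solved with a multilevel
    matrix-free Gauss-Newton method. Displacement vectors are cropped to the
    meniscal masks, each meniscus is partitioned into anterior horn,
    intermediate part and posterior horn by equal centerline arc length, and
    mean motion is decomposed along medio-lateral and anterior-posterior axes
    obtained by principal component analysis of the unloaded meniscal voxels.
    A synthetic knee phantom generator with analytically known ground-truth
    motion supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
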