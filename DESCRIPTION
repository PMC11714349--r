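Package: plsrmap
Title: Latent Encoding Models for Cortical Surface Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits partial least squares regression (PLSR) encoding models that
    link a low-dimensional behavioral stimulus embedding to vertex-wise
    responses on cortical surface meshes. Provides cross-validated prediction
    (R-squared) maps with maximum-statistic permutation inference controlling
    familywise error, surface-based searchlight pairwise decoding, loading
    reproducibility via a held-out GLM, hemispheric mirror-symmetry analysis,
    latent-score/property-rating correlations with Holm adjustment,
    representational similarity analysis against layer activations, a full
    linear-regression baseline, and a synthetic surface-data generator with
    known latent ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
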