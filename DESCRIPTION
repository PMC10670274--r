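Package: mfxbmd
Title: Multifidus CT Texture Features for Opportunistic BMD and BMC Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a 45-element histogram and gray-level co-occurrence
    matrix (GLCM) texture feature vector from multifidus-muscle regions of
    interest on axial spinal CT slices, fuses left and right sides into 90
    features per case, and fits ordinary least squares and LASSO linear
    regressions predicting DXA-measured bone mineral density (BMD) and bone
    mineral content (BMC) at the total lumbar spine and total hip. Includes a
    seeded synthetic cohort generator (paired textured pseudo-CT slices with
    a known latent-texture-to-DXA linear truth), study-style cohort exclusion
    filtering, cross-validated evaluation, and a reproducible end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2,
    rlang,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
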