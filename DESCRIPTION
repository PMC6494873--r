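Package: cytofuse
Title: Multi-Panel Flow Cytometry Fusion with Histogram Fingerprints and
    OPLS-DA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fuses multicolour flow cytometry panels measured in separate
    aliquots of the same samples into a single discriminant model.  Each
    sample is summarised per aliquot as a smoothed, unit-sum 2D histogram
    of cells in a per-aliquot PCA score space; the unfolded histograms of
    all aliquots are concatenated into one fused matrix and classified
    with OPLS-DA.  Variable importance in projection (VIP) sparsifies the
    predictive weights, which refold into per-aliquot leukocyte maps for
    interpretation.  Includes repeated stratified double cross-validation
    with stored splits, permutation testing, leave-one-panel-out accuracy
    contributions, self-organising-map comparator pipelines, a synthetic
    multi-panel study generator with known ground truth, and minimal FCS
    and CSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    glmnet,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
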