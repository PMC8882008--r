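Package: petpls
Title: Brain-Behaviour Partial Least Squares Correlation for Amyloid PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis chain for relating the regional distribution of
    beta-amyloid deposition to cognitive performance. Computes parametric
    distribution volume ratio (DVR) images from dynamic PET via multilinear
    reference tissue modelling (MRTM/MRTM2), assembles masked subjects-by-
    voxels data matrices, fits brain-behaviour partial least squares
    correlation (PLS-C) by singular value decomposition of the cross-block
    correlation matrix, validates latent variables by permutation testing
    and voxel saliences by bootstrap resampling (bootstrap salience ratios),
    extracts supra-threshold clusters with stereotaxic coordinate reporting,
    and provides the accompanying univariate group statistics. A synthetic
    data generator with planted latent structure supports calibration and
    recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
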