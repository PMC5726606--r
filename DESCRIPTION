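Package: tractterm
Title: Tract Termination Mapping on the Grey-White Interface with
    Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic streamline tractography from grey-white interface
    seed voxels, construction of raw and statistical (pairwise-evidence)
    cortical termination maps, and permutation-null overlap statistics
    linking termination regions to functional-domain maps.  Includes a
    synthetic volumetric phantom generator with known tract geometry and
    ground-truth terminations so the full pipeline is testable end to end:
    grey-white interface seed extraction, probabilistic index of
    connectivity (PICo) style streamline propagation with exclusion-mask,
    length and curvature stopping rules, per-seed termination proportions,
    Gaussian smoothing and group averaging, voxelwise sign-flip
    maximum-statistic familywise-error permutation comparisons summed into
    evidence maps, and region-overlap tests against a random grey-matter
    voxel null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
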