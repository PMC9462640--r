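Package: ortcva
Title: Ordinal Trend Covariance Pattern Analysis for Resting-State fALFF Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives treatment-responsive spatial covariance brain networks
    from paired pre/post resting-state fMRI scans using ordinal trend
    canonical variates analysis (OrT/CVA) on fractional amplitude of
    low-frequency fluctuation (fALFF) maps. Provides permutation inference
    on the ordinal-trend violator count, bootstrap voxel-reliability z-maps,
    leave-one-out validation, prospective pattern-expression scoring
    (topographic profile rating), atlas-based and cluster-extent regional
    characterization, longitudinal mixed-model and effect-size statistics
    linking expression to clinical tremor ratings, and imaging
    transcriptomics via first-component partial least squares with shuffle
    and spin permutation nulls, bootstrap gene ranking, and hypergeometric
    gene-set over-representation. Includes a synthetic-cohort generator
    with known ground truth (4D series, masks, atlases, clinical scores,
    regional gene expression) so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    lme4,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
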