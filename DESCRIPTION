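Package: wscoremap
Title: Normative W-Score Mapping and Mass-Univariate Inference for
    Small-Vessel-Disease Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Covariate-adjusted normative modelling of brain maps for
    small-vessel-disease cohorts. Fits per-location regressions of cortical
    thickness and DTI skeleton measures (FA, MD) on age, sex and intracranial
    volume in a control cohort, converts patient maps to W-score deviation
    maps, builds white-matter-hyperintensity lesion-frequency maps, and runs
    mass-univariate group contrasts with Benjamini-Hochberg FDR correction on
    surface vertices and max-statistic permutation family-wise-error
    correction on skeleton voxels, plus global-mean ANCOVA with Bonferroni
    post hoc tests. A synthetic-cohort generator with known ground truth
    drives every stage at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
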