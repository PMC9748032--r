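Package: lesionfit3d
Title: Automated 3D Prostate Lesion Measurement by Constrained Ellipsoid Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated three-dimensional measurement of prostate lesions from
    binary segmentation masks on anisotropic MRI voxel grids. Stacked per-slice
    regions of interest are interpolated to fine (1 mm) slices by shape-based
    signed-distance interpolation, surface samples are fitted with an
    ellipsoid-specific least-squares quadric under the kJ - I^2 = 1 constraint,
    and tumour maximum diameter and volume are derived from the fitted
    ellipsoid. Also provides the radiologist-style two-dimensional reference
    measurements (planimetric volume, axial Feret diameter), the PI-RADS v2.1
    1.5 cm size-criterion rescoring rule, method-agreement statistics
    (Bland-Altman, paired t, Pearson correlation, Lilliefors normality), and
    seeded phantom and cohort generators for validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    nortest,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
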