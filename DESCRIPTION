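Package: boldvigil
Title: Linking Trial-by-Trial Reaction-Time Fluctuations to BOLD Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for sustained-attention (vigilance) task fMRI:
    a parametric general linear model in which trial-onset regressors are
    modulated by reaction time, and a voxelwise lagged cross-correlation
    between the reaction-time series and the BOLD signal over lags of
    -50 to +50 seconds, with Fisher-Z transformation, run averaging, and
    group-level windowed contrasts. Includes a full synthetic-data module
    (task sequencing for a grid-based continuous-performance task with rare
    knight-move target trials, an autocorrelated latent vigilance process
    driving reaction times, and BOLD runs with voxels coupled to behavior
    with known sign and temporal lead) so that every analysis stage can be
    verified by parameter recovery on data with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
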