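Package: levelmix
Title: Clustering Linear Growth Trajectories with Random-Intercept Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Likelihood-based cluster analysis for balanced longitudinal
    panels of areal units whose outcome grows linearly in time, such as
    regional life expectancy series.  The outcome trajectories are modelled
    as straight lines with a slope shared across all units and a latent
    finite mixture over the intercepts (a nonparametric, discrete random
    intercept).  Parameters are estimated by an EM algorithm with closed-form
    updates, the number of mixture components is chosen by BIC, and units are
    assigned to components by the maximum-posterior (MAP) rule.  Includes
    extensions with component-specific slopes or variances and a quadratic
    time trend with a likelihood-ratio test, Pearson chi-square association
    tests of the classification against a binary covariate, cross-run
    classification concordance, a generative simulator with a
    parameter-recovery harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
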