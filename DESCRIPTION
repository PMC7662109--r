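Package: glildscore
Title: Semi-Quantitative Chest CT Scoring for Granulomatous Lymphocytic
    Interstitial Lung Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements two semi-quantitative chest computed-tomography
    scoring systems for common variable immunodeficiency disorders (the
    whole-lung Baumann method and the lobe-wise Hartmann method) as
    data-driven scoring schemas, together with the evaluation machinery
    needed to use them as study outcome measures: component and composite
    scores expressed as percent of maximum (with severity multipliers for
    bronchiectasis and bronchial wall thickening), radiological
    phenotyping of GLILD and airway disease, inter- and intra-observer
    agreement via the two-way mixed-effects consistency intraclass
    correlation coefficient, longitudinal trend models (random-intercept
    linear mixed models and exchangeable generalized estimating
    equations) with a likelihood-ratio test for nonlinearity, and a
    synthetic cohort generator with known ground truth for validating the
    whole pipeline without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
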