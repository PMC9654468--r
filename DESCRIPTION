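Package: dhqvalidate
Title: Validation Toolkit for Diet-Quality Questionnaire Scores Against
    Repeated 24-h Recalls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores a 24-item diet habits questionnaire into eight dietary
    sub-scores and a 20-100 total, converts repeated 24-h dietary recall
    records into nutrient totals and dietary-guideline food-group serves
    (including composite-food deconstruction and discretionary serve rules),
    estimates usual (habitual) intake with a two-part shrinkage model
    (Box-Cox variance components plus beta-binomial consumption
    probabilities), and evaluates construct validity and internal
    consistency with Spearman correlations, quartile trend regression,
    normality-gated group comparisons and Cronbach's alpha.  Data-driven
    dietary patterns are extracted by correlation-matrix principal component
    analysis with sampling-adequacy diagnostics, varimax rotation,
    regression factor scores and loading-based food-group attribution.  A
    synthetic cohort generator with known ground truth (latent diet-quality
    trait, episodic intake, planted factor structure) makes every stage
    testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
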