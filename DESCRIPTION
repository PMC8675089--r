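Package: trustgame
Title: Guilt and Inequity Aversion Analysis for Binary Trust-Game Choices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for model-based analysis of Cooperate/Defect decisions in a
    belief-dependent trust game. Generates 45-trial task designs with
    near-orthogonal Reward, Guilt and Inequity regressors; implements a utility
    family combining guilt aversion (sensitivity to disappointing a partner's
    revealed expectation) and Fehr-Schmidt style inequity aversion; fits
    per-participant logistic choice models by Firth's bias-reduced penalized
    likelihood; selects among ten candidate models by repeated three-fold
    cross-validated predictive likelihood and BIC; and provides group-level
    inference (Welch contrasts, questionnaire correlations, covariate-by-sex
    interaction regression, and bootstrap mediation of sex differences through
    a scalar connectivity mediator). Includes a synthetic-cohort generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
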