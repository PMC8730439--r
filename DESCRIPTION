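Package: psyecon
Title: Psycho-Economic Predictors of Compliance with Protective Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how psycho-economic dispositions predict
    compliance with public-health restrictions. Implements the three
    behavioural-economics elicitation designs (intertemporal choice, risk
    lottery, mixed-gamble loss series), per-subject maximum-likelihood
    estimation of quasi-hyperbolic (beta-delta), hyperbolic and exponential
    delay discounting with model comparison, count-based switching-point
    estimation for titrated risk and loss series, psychometric scale scoring
    with Cronbach's alpha reliability, a calibrated synthetic survey-cohort
    generator (latent traits, one-factor item responses, task choices,
    zero-clustered Tweedie outcomes), and the compliance-prediction stage:
    standardized multiple regression with a full diagnostic battery (VIF,
    tolerance, Cook's distance, Durbin-Watson, residual normality, partial
    eta squared, observed power) plus a Tweedie generalized linear model
    fitted by iteratively reweighted least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    car,
    lmtest,
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
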