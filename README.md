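# psyecon

Predicting compliance with public-health restrictions from
psycho-economic dispositions: an R implementation of the full analysis
pipeline for lockdown-era survey studies that combine behavioural
economics tasks (delay discounting, risk aversion, loss aversion) with
psychometric instruments (locus of control, moral foundations,
temperament) to explain who stays home and who doesn't.

It is written for quantitative behavioural scientists who want each
stage of such a study as a tested, reusable component — from the trial
grids shown to participants all the way to the regression tables — and
for methodologists who want to probe those stages by parameter recovery
on a calibrated synthetic cohort.

## What it implements

**Task designs.** Deterministic constructors for the three elicitation
series: 24 intertemporal trials (immediate 50–90 vs delayed 55–110 units
at 7/30/60/90 days), a 19-trial risk lottery (safe 10–190 vs a 50/50
lottery over 300; expected value 150), and 29 mixed gambles (gain 55–195
vs lose 50, all with positive expected value).

**Delay discounting.** Per-subject maximum likelihood for three discount
functions — quasi-hyperbolic *U = β δᵈ A* (the beta-delta model:
δ the per-day discount factor, β < 1 a present bias), hyperbolic
*U = A/(1+kd)*, and exponential *U = A δᵈ* — under a logistic choice rule
P(delayed) = logistic((U_delayed − U_immediate)/τ), fitted by a
deterministic grid plus Nelder–Mead refinement, with per-subject fit
statistics and cohort-level model comparison.

**Titration switching points.** A count-based, order-invariant estimator
of the preference switching point in the risk and loss series, robust to
non-monotone responders, with gain/loss and gamble/safe indifference
ratios (a risk-neutral agent switches at safe 150: ratio 300/150 = 2;
the canonical loss-averse switch at gain 100: ratio 100/50 = 2).

**Scales.** Configurable scoring (reverse-keying, sum/mean aggregation,
internal−external difference) for the locus-of-control, moral-foundations
and temperament instruments, plus Cronbach's alpha.

**Synthetic cohort.** A seeded generator reproducing the published data
structure: demographics, correlated latent traits, one-factor item
responses calibrated to reliability targets, task responses, and four
compliance outcomes — one Gaussian rating and three zero-clustered
right-skewed quantities drawn from a compound Poisson-gamma (Tweedie)
distribution on a log link.

**Compliance regressions.** Standardized multiple regression with the
full diagnostic battery (partial η², post-hoc observed power, VIF,
tolerance, Durbin–Watson, Kolmogorov–Smirnov residual normality, Cook's
distance) and a confirmatory Tweedie GLM (variance μ^p, log link) fitted
by iteratively reweighted least squares with Wald inference — authored in
the package and cross-checked against independent implementations in the
test suite.

See `vignettes/compliance-pipeline.Rmd` for the models, calibration
choices and their rationale.

## Worked example

Fit one simulated subject, estimate a switching point, then run the whole
pipeline on a 269-respondent synthetic cohort:

```r
library(psyecon)

design <- delay_design()
set.seed(42)
choices <- simulate_choices(design, "beta_delta",
                            beta = 0.89, delta = 0.99, temperature = 2)
fit_discount(choices, "beta_delta")
#> Discounting fit (beta_delta), 24 trials
#>        beta       delta temperature
#>      0.8179      0.9927      1.0864
#> logLik -1.756 | fit R2 0.808 | McFadden R2 0.838 | converged: TRUE
```

From 24 binary choices the estimator recovers a present bias of 0.82
(truth 0.89) and a daily discount factor of 0.993 (truth 0.99); `fit R2`
is the squared correlation between fitted choice probabilities and the
observed choices.

```r
loss <- loss_design()
resp <- data.frame(gain_amount = loss$trials$gain_amount,
                   accepted_gamble = loss$trials$gain_amount >= 100)
estimate_switch(resp, loss)
#> Titration switch (loss): level 100, ratio 2.000, averse; 1 reversal(s)
```

A responder who accepts gambles only from gain 100 upward is loss-averse
with the canonical gain/loss indifference ratio of 2.

```r
cfg <- cohort_config(n_participants = 269, n_incomplete = 25)
run_pipeline(cfg, seed = 1, out_dir = "run1")
#> [simulate] 269 participants generated (244 complete, 25 dropped: incomplete data)
#> [score] 25132 item responses -> 244 scored participants
#> [fit-choices] 244 subjects x 3 models fitted
#> [titrate] 488 switch results
#> [analyze] analysis table: 244 rows, 16 columns
#> [analyze] 4 OLS + 3 Tweedie models fitted
#> [report] 8 table files written

tab <- read.csv("run1/table_times_left_home_ols.csv")
tab[tab$significant, c("predictor", "standardized_beta", "t", "p_value", "vif")]
#>      predictor standardized_beta     t  p_value  vif
#>            age             0.236  3.80 0.000186 1.02
#>  mfq_authority            -0.146 -2.34 0.020388 1.04
#>        dd_beta            -0.177 -2.84 0.004878 1.02
```

At the emulated sample size (244 analysable respondents) the generating
effects of age (+0.267) and authority (−0.167) on times-left-home come
back significant with the right signs; the locus-of-control effect
misses the 0.05 cut in this particular cohort and one null predictor is
flagged by chance — exactly the small-sample behaviour one should expect
with standardized effects near 0.15 and eleven predictors. The test
suite verifies full sign recovery at ten times this sample size.

The same pipeline is available from the shell:

```sh
Rscript scripts/pipeline.R --seed 1 --out run1
```

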