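make_data <- function(n = 120, seed = 17) {
  set.seed(seed)
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  g = sample(c("female", "male"), n, replace = TRUE))
  d$y <- 0.5 * d$x1 - 0.3 * d$x2 + rnorm(n)
  d
}

test_that("standardized OLS matches the normal-equations closed form", {
  d <- make_data()
  fit <- fit_compliance_ols(d, "y", c("x1", "x2", "x3"))
  Z <- scale(d[, c("x1", "x2", "x3")])
  yz <- drop(scale(d$y))
  X <- cbind(1, Z)
  b <- solve(crossprod(X), crossprod(X, yz))
  expect_equal(fit$coefficients$standardized_beta, unname(b[-1]),
               tolerance = 1e-10)
  # F statistic identity
  r2 <- fit$model$r_squared
  k <- 3; n <- fit$n
  expect_equal(fit$model$f_statistic, (r2 / k) / ((1 - r2) / (n - k - 1)),
               tolerance = 1e-10)
})

test_that("a single-predictor standardized beta is the Pearson correlation", {
  d <- make_data()
  fit <- fit_compliance_ols(d, "y", "x1")
  expect_equal(fit$coefficients$standardized_beta, cor(d$y, d$x1),
               tolerance = 1e-10)
  expect_equal(fit$coefficients$vif, 1.0)
  # perfect fit degenerates cleanly
  d$z <- d$x1
  fit2 <- suppressWarnings(fit_compliance_ols(d, "z", "x1"))
  expect_equal(fit2$coefficients$standardized_beta, 1, tolerance = 1e-10)
  expect_equal(fit2$model$r_squared, 1, tolerance = 1e-10)
})

test_that("VIF and tolerance match independent auxiliary regressions", {
  d <- make_data()
  d$x4 <- 0.8 * d$x1 + 0.6 * rnorm(nrow(d))       # induced collinearity
  preds <- c("x1", "x2", "x3", "x4")
  fit <- fit_compliance_ols(d, "y", preds)
  Z <- scale(d[, preds])
  for (j in seq_along(preds)) {
    aux <- lm(Z[, j] ~ Z[, -j])
    vif_j <- 1 / (1 - summary(aux)$r.squared)
    expect_equal(fit$coefficients$vif[j], vif_j, tolerance = 1e-10)
    expect_equal(fit$coefficients$tolerance[j], 1 / vif_j, tolerance = 1e-10)
  }
})

test_that("VIF agrees with the car implementation", {
  skip_if_not_installed("car")
  d <- make_data()
  d$x4 <- 0.8 * d$x1 + 0.6 * rnorm(nrow(d))
  preds <- c("x1", "x2", "x3", "x4")
  fit <- fit_compliance_ols(d, "y", preds)
  ref <- car::vif(lm(y ~ x1 + x2 + x3 + x4, d))
  expect_equal(unname(fit$coefficients$vif), unname(ref), tolerance = 1e-8)
})

test_that("effect sizes and observed power behave like their F-based definitions", {
  d <- make_data(n = 244)
  fit <- fit_compliance_ols(d, "y", c("x1", "x2", "x3"))
  co <- fit$coefficients
  expect_true(all(co$partial_eta_squared > 0 & co$partial_eta_squared < 1))
  expect_true(all(co$observed_power > 0 & co$observed_power <= 1))
  # power is monotone in the absolute t statistic
  o <- order(abs(co$t))
  expect_true(all(diff(co$observed_power[o]) >= 0))
  # worked check at the reporting convention: t = 2.223, df = 240
  expect_lt(abs(2.223^2 / (2.223^2 + 240) - 0.0202), 1e-4)
  pw <- pf(qf(0.95, 1, 240), 1, 240, ncp = 2.223^2, lower.tail = FALSE)
  expect_lt(abs(pw - 0.600), 0.005)
})

test_that("Durbin-Watson matches its definition, limits and lmtest", {
  n <- 50
  e <- rep(c(1, -1), length.out = n)              # maximal alternation
  expect_equal(durbin_watson(e), 4 * (n - 1) / n)
  expect_equal(durbin_watson(rep(1, 10) * (1:10)), durbin_watson(1:10))
  d <- make_data()
  fit <- fit_compliance_ols(d, "y", c("x1", "x2"))
  skip_if_not_installed("lmtest")
  ref <- lmtest::dwtest(fit$lm)
  expect_equal(fit$diagnostics$durbin_watson, unname(ref$statistic),
               tolerance = 1e-10)
})

test_that("Cook's distances equal brute-force leave-one-out refits", {
  d <- make_data(n = 50)
  fit <- fit_compliance_ols(d, "y", c("x1", "x2"))
  zd <- data.frame(y = drop(scale(d$y)), x1 = drop(scale(d$x1)),
                   x2 = drop(scale(d$x2)))
  loo <- oracle_cooks_loo(y ~ x1 + x2, zd)
  expect_equal(fit$diagnostics$cooks_distance, unname(loo), tolerance = 1e-8)
  expect_equal(fit$diagnostics$max_cooks_distance,
               max(fit$diagnostics$cooks_distance))
})

test_that("degenerate designs and inputs raise informative errors", {
  d <- make_data()
  d$dup <- d$x1
  expect_error(fit_compliance_ols(d, "y", c("x1", "dup")), "rank-deficient")
  expect_error(fit_compliance_ols(d, "y", character(0)))
  expect_error(fit_compliance_ols(d[1:3, ], "y", c("x1", "x2", "x3")),
               "complete cases")
  d$const <- 1
  expect_error(fit_compliance_ols(d, "y", "const"), "constant")
  expect_error(fit_compliance_ols(d, "nope", "x1"), "lacks column")
})

test_that("binary predictors are coded and standardized", {
  d <- make_data(n = 200)
  d$y <- d$y + 0.8 * (d$g == "male")
  fit <- fit_compliance_ols(d, "y", c("g", "x1"))
  expect_gt(fit$coefficients$standardized_beta[1], 0)  # second sorted level = 1
  expect_lt(fit$coefficients$p_value[1], 0.01)
})

test_that("report tables are deterministic and carry significance flags", {
  d <- make_data(n = 150)
  d$yy <- rnorm(150)          # null outcome: no flagged rows expected
  f1 <- fit_compliance_ols(d, "y", c("x1", "x2"))
  f0 <- fit_compliance_ols(d, "yy", c("x3"))
  set.seed(18)
  d$ct <- rtweedie_cp(150, exp(0.5 + 0.4 * d$x1), phi = 2, power = 1.5)
  ft <- fit_compliance_tweedie(d, "ct", c("x1", "x2"))
  tabs <- report_tables(list(f1, f0, ft))
  expect_equal(nrow(tabs$models), 3L)
  expect_true("tweedie" %in% tabs$models$family)
  expect_false(any(tabs$coefficients$significant[tabs$coefficients$outcome == "yy"]))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  files1 <- write_report_tables(list(f1, f0, ft), dir1)
  files2 <- write_report_tables(list(f1, f0, ft), dir2)
  expect_identical(lapply(files1, readLines), lapply(files2, readLines))
})
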