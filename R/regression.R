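#' Durbin-Watson statistic
#'
#' `d = sum((e_i - e_{i-1})^2) / sum(e_i^2)` over residuals in their input
#' row order; values near 2 indicate independent residuals, near 0 positive
#' and near 4 negative first-order autocorrelation. On unordered survey
#' data the statistic depends on the (arbitrary) row order of the input
#' file; it is reported in that order, as is conventional.
#'
#' @param residuals numeric residual vector, in input row order.
#' @return scalar in \[0, 4\].
#' @export
durbin_watson <- function(residuals) {
  sum(diff(residuals)^2) / sum(residuals^2)
}

# VIF of each column of a (no-intercept) predictor matrix, by regressing
# each predictor on all the others (with intercept): VIF_j = 1/(1 - R2_j).
vif_auxiliary <- function(Z) {
  p <- ncol(Z)
  if (p == 1L) return(stats::setNames(1, colnames(Z)))
  vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, Z[, -j, drop = FALSE]), Z[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((Z[, j] - mean(Z[, j]))^2)
    1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(Z))
}

z_score <- function(x) {
  if (is.logical(x)) x <- as.numeric(x)
  if (is.character(x) || is.factor(x)) {
    lev <- sort(unique(as.character(x)))
    if (length(lev) != 2)
      stop("non-numeric predictors must be binary to be z-scored")
    x <- as.numeric(as.character(x) == lev[2])
  }
  s <- stats::sd(x)
  if (s == 0) stop("constant variable cannot be z-scored")
  (x - mean(x)) / s
}

#' Standardized multiple regression with the full diagnostic battery
#'
#' The compliance-prediction stage: outcome and predictors are z-scored
#' (binary predictors 0/1-coded first) and fitted by ordinary least
#' squares, so the coefficients are standardized betas. Each coefficient
#' row carries `t`, two-sided `p`, partial eta squared
#' (`t^2 / (t^2 + residual df)`), post-hoc observed power at the observed
#' noncentrality (`t^2`) under the noncentral F distribution at
#' `alpha_level`, the variance inflation factor from auxiliary regressions,
#' and its reciprocal tolerance. The model block carries R-squared, the F
#' test, and the assumption diagnostics: Durbin-Watson on residuals in
#' input row order, a Kolmogorov-Smirnov test of the residuals against a
#' normal with their own mean/sd, and the maximum Cook's distance, with
#' flags at the conventional thresholds (Cook's D >= 1, VIF >= 2,
#' tolerance <= 0.2).
#'
#' @param data wide participant table (one row per participant).
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names.
#' @param alpha_level significance threshold used for flags and observed
#'   power (default 0.05).
#' @return An object of class `compliance_ols` with elements `model`
#'   (R-squared, F, dfs, p), `coefficients` (one row per predictor),
#'   `diagnostics` (Durbin-Watson, KS p, max Cook's distance, flags),
#'   `residuals`, `fitted`, `lm` (the underlying z-scored [stats::lm()]
#'   fit), `n`, `outcome`, `predictors`, `alpha_level`. Methods: `print`,
#'   `summary`, `coef`, `residuals`, `fitted`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
#' d$y <- 0.4 * d$x1 + rnorm(100)
#' fit_compliance_ols(d, "y", c("x1", "x2"))
#' @export
fit_compliance_ols <- function(data, outcome, predictors, alpha_level = 0.05) {
  stopifnot(length(predictors) >= 1, alpha_level > 0, alpha_level < 1)
  cols <- c(outcome, predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[, cols])
  d <- data[cc, cols, drop = FALSE]
  n <- nrow(d)
  if (n <= length(predictors) + 1)
    stop(sprintf("need more than %d complete cases to fit %d predictors (got %d)",
                 length(predictors) + 1, length(predictors), n))
  Z <- vapply(predictors, function(p) z_score(d[[p]]), numeric(n))
  colnames(Z) <- predictors
  yz <- z_score(d[[outcome]])
  X <- cbind(`(Intercept)` = 1, Z)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear predictor set includes: ",
         paste(aliased, collapse = ", "))
  }
  df_fit <- as.data.frame(cbind(.y = yz, Z))
  lmfit <- stats::lm(.y ~ ., data = df_fit)
  sm <- summary(lmfit)
  ct <- sm$coefficients[predictors, , drop = FALSE]
  df_res <- lmfit$df.residual
  tval <- ct[, "t value"]
  pval <- ct[, "Pr(>|t|)"]
  eta2 <- tval^2 / (tval^2 + df_res)
  fcrit <- stats::qf(1 - alpha_level, 1, df_res)
  # the noncentral F tail is numerically 1 long before pnbeta can struggle
  power <- vapply(tval^2, function(ncp) {
    if (ncp > 2500) 1
    else stats::pf(fcrit, 1, df_res, ncp = ncp, lower.tail = FALSE)
  }, numeric(1))
  vif <- vif_auxiliary(Z)
  coefs <- data.frame(predictor = predictors,
                      standardized_beta = unname(ct[, "Estimate"]),
                      t = unname(tval), p_value = unname(pval),
                      partial_eta_squared = unname(eta2),
                      observed_power = unname(power),
                      vif = unname(vif), tolerance = unname(1 / vif),
                      significant = unname(pval < alpha_level))
  r2 <- sm$r.squared
  k <- length(predictors)
  fstat <- (r2 / k) / ((1 - r2) / (n - k - 1))
  model_p <- stats::pf(fstat, k, n - k - 1, lower.tail = FALSE)
  e <- stats::residuals(lmfit)
  dw <- durbin_watson(e)
  ks <- suppressWarnings(stats::ks.test(e, "pnorm", mean(e), stats::sd(e)))
  cooks <- stats::cooks.distance(lmfit)
  diagnostics <- list(durbin_watson = dw, ks_p = ks$p.value,
                      cooks_distance = unname(cooks),
                      max_cooks_distance = max(cooks),
                      flags = list(outliers = any(cooks >= 1),
                                   collinearity = any(vif >= 2 | 1 / vif <= 0.2),
                                   nonnormal_residuals = ks$p.value < alpha_level))
  structure(list(model = list(r_squared = r2, f_statistic = fstat,
                              df1 = k, df2 = n - k - 1, p_value = model_p),
                 coefficients = coefs, diagnostics = diagnostics,
                 residuals = unname(e), fitted = unname(stats::fitted(lmfit)),
                 lm = lmfit, n = n, outcome = outcome,
                 predictors = predictors, alpha_level = alpha_level),
            class = "compliance_ols")
}

#' @export
print.compliance_ols <- function(x, ...) {
  m <- x$model
  cat(sprintf("Standardized OLS: %s ~ %s\n", x$outcome,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("R2 = %.3f, F(%d, %d) = %.3f, p = %.3g, n = %d\n",
              m$r_squared, m$df1, m$df2, m$f_statistic, m$p_value, x$n))
  print(x$coefficients, row.names = FALSE, digits = 3)
  d <- x$diagnostics
  cat(sprintf("Durbin-Watson %.3f | KS p %.3f | max Cook's D %.3f\n",
              d$durbin_watson, d$ks_p, d$max_cooks_distance))
  invisible(x)
}

#' @export
summary.compliance_ols <- function(object, ...) {
  object
}

#' @export
coef.compliance_ols <- function(object, ...) {
  stats::setNames(object$coefficients$standardized_beta,
                  object$coefficients$predictor)
}

#' @export
residuals.compliance_ols <- function(object, ...) object$residuals

#' @export
fitted.compliance_ols <- function(object, ...) object$fitted

#' Tweedie confirmatory model for one compliance outcome
#'
#' Wraps [tweedie_glm()] for the compliance table: fits the outcome on the
#' given predictors (raw scale, log link) and returns a report mirroring
#' the OLS one. Intended for the right-skewed, zero-clustered outcomes;
#' the approximately normal perceived-risk outcome stays with OLS.
#'
#' @inheritParams fit_compliance_ols
#' @param power Tweedie variance power in (1, 2).
#' @param ci_level Wald confidence level (default 0.95).
#' @return An object of class `compliance_tweedie`: `coefficients` table
#'   (B, SE, Wald, p, CI), `fit` (the `tweedie_glm`), `n`, `outcome`,
#'   `predictors`.
#' @export
fit_compliance_tweedie <- function(data, outcome, predictors, power = 1.5,
                                   ci_level = 0.95, alpha_level = 0.05) {
  cols <- c(outcome, predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[, cols])
  d <- data[cc, cols, drop = FALSE]
  for (p in predictors) if (!is.numeric(d[[p]])) d[[p]] <- z_score(d[[p]]) # binary -> coded
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- tweedie_glm(fml, d, power = power, ci_level = ci_level)
  keep <- setdiff(names(fit$coefficients), "(Intercept)")
  tab <- data.frame(predictor = keep,
                    B = unname(fit$coefficients[keep]),
                    se = unname(fit$se[keep]),
                    wald = unname(fit$wald[keep]),
                    p_value = unname(fit$p_value[keep]),
                    ci_lower = unname(fit$ci_lower[keep]),
                    ci_upper = unname(fit$ci_upper[keep]),
                    significant = unname(fit$p_value[keep] < alpha_level))
  structure(list(coefficients = tab, fit = fit, n = nrow(d),
                 outcome = outcome, predictors = predictors,
                 power = power, ci_level = ci_level,
                 alpha_level = alpha_level),
            class = "compliance_tweedie")
}

#' @export
print.compliance_tweedie <- function(x, ...) {
  cat(sprintf("Tweedie GLM (power %.3g): %s ~ %s, n = %d\n", x$power,
              x$outcome, paste(x$predictors, collapse = " + "), x$n))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Assemble report tables from fitted compliance models
#'
#' Collects one or more `compliance_ols` / `compliance_tweedie` fits into
#' machine-readable tables: a per-model summary (whole-model statistics
#' and diagnostics) and a per-coefficient table with significance flags.
#' Serialization is deterministic — the same reports produce byte-identical
#' files.
#'
#' @param reports list of fitted models (named by outcome if desired).
#' @return list with data frames `models` and `coefficients`.
#' @export
report_tables <- function(reports) {
  if (!length(reports)) stop("no reports to tabulate")
  models <- list(); coefs <- list()
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    if (inherits(r, "compliance_ols")) {
      models[[i]] <- data.frame(outcome = r$outcome, family = "gaussian_ols",
                                n = r$n, r_squared = r$model$r_squared,
                                f_statistic = r$model$f_statistic,
                                df1 = r$model$df1, df2 = r$model$df2,
                                model_p = r$model$p_value,
                                durbin_watson = r$diagnostics$durbin_watson,
                                ks_p = r$diagnostics$ks_p,
                                max_cooks_distance = r$diagnostics$max_cooks_distance)
      tab <- r$coefficients
      tab <- cbind(outcome = r$outcome, family = "gaussian_ols", tab)
      coefs[[i]] <- tab
    } else if (inherits(r, "compliance_tweedie")) {
      models[[i]] <- data.frame(outcome = r$outcome, family = "tweedie",
                                n = r$n, r_squared = NA_real_,
                                f_statistic = NA_real_, df1 = NA_real_,
                                df2 = NA_real_, model_p = NA_real_,
                                durbin_watson = NA_real_, ks_p = NA_real_,
                                max_cooks_distance = NA_real_)
      tab <- cbind(outcome = r$outcome, family = "tweedie", r$coefficients)
      coefs[[i]] <- tab
    } else stop("unsupported report object of class ", class(r)[1])
  }
  all_names <- unique(unlist(lapply(coefs, names)))
  coefs <- lapply(coefs, function(tb) {
    for (nm in setdiff(all_names, names(tb))) tb[[nm]] <- NA
    tb[, all_names]
  })
  list(models = do.call(rbind, models),
       coefficients = do.call(rbind, coefs))
}

#' Write per-model report tables as CSV files
#'
#' One CSV per fitted model (`<prefix><outcome>_<family>.csv` with the
#' coefficient rows) plus `<prefix>models.csv` with whole-model statistics.
#'
#' @param reports list of fitted compliance models.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "table_").
#' @return character vector of files written, invisibly.
#' @export
write_report_tables <- function(reports, dir, prefix = "table_") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- report_tables(reports)
  files <- character(0)
  for (r in reports) {
    fam <- if (inherits(r, "compliance_ols")) "ols" else "tweedie"
    f <- file.path(dir, sprintf("%s%s_%s.csv", prefix, r$outcome, fam))
    sub <- tabs$coefficients[tabs$coefficients$outcome == r$outcome &
                             tabs$coefficients$family ==
                               (if (fam == "ols") "gaussian_ols" else "tweedie"), ]
    utils::write.csv(sub, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, paste0(prefix, "models.csv"))
  utils::write.csv(tabs$models, f, row.names = FALSE, quote = FALSE)
  invisible(c(files, f))
}
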