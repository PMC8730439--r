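test_that("discounted utilities match their closed forms", {
  # present bias alone: delta = 1 isolates the beta down-weighting
  expect_equal(discount_utility(100, 30, "beta_delta", beta = 0.89, delta = 1), 89)
  # identity at zero delay for every model
  expect_equal(discount_utility(70, 0, "beta_delta", beta = 0.5, delta = 0.95), 70)
  expect_equal(discount_utility(70, 0, "hyperbolic", k = 0.1), 70)
  expect_equal(discount_utility(70, 0, "exponential", delta = 0.9), 70)
  expect_equal(discount_utility(110, 90, "hyperbolic", k = 0.01), 110 / 1.9)
  expect_equal(discount_utility(80, 10, "exponential", delta = 0.99), 80 * 0.99^10)
  expect_error(discount_utility(100, -1, "exponential", delta = 0.99), "non-negative")
  expect_error(discount_utility(100, 5, "hyperbolic", k = -0.1), ">= 0")
})

test_that("the logistic choice rule respects its symmetry, limits and monotonicity", {
  tr <- data.frame(immediate_amount = 50, delayed_amount = 50 / 0.9,
                   delay_days = 0)
  # equal utilities -> exactly 0.5 (delay 0: delayed utility is the amount)
  tr0 <- data.frame(immediate_amount = 60, delayed_amount = 60, delay_days = 0)
  expect_equal(choice_probability(tr0, "beta_delta", beta = 0.8, delta = 0.95), 0.5)
  # deterministic limit as temperature -> 0+
  trd <- data.frame(immediate_amount = 50, delayed_amount = 70, delay_days = 7)
  p <- choice_probability(trd, "beta_delta", beta = 1, delta = 1,
                          temperature = 1e-6)
  expect_gt(p, 1 - 1e-12)
  # undiscounting subject always favours the (strictly larger) delayed reward
  d <- delay_design()
  p_all <- choice_probability(d, "beta_delta", beta = 1, delta = 1, temperature = 2)
  expect_true(all(p_all > 0.5))
  expect_true(all(p_all > 0 & p_all < 1))
  # monotone in delayed amount, antitone in delay when discounting
  grid <- data.frame(immediate_amount = 50, delayed_amount = c(60, 80, 100),
                     delay_days = 30)
  expect_true(all(diff(choice_probability(grid, "beta_delta", beta = 0.9,
                                          delta = 0.99, temperature = 2)) > 0))
  grid2 <- data.frame(immediate_amount = 50, delayed_amount = 80,
                      delay_days = c(7, 30, 90))
  expect_true(all(diff(choice_probability(grid2, "hyperbolic", k = 0.02,
                                          temperature = 2)) < 0))
  expect_error(choice_probability(grid, "beta_delta", beta = 1, delta = 1,
                                  temperature = 0), "positive")
})

test_that("beta-delta nests the exponential model at beta = 1", {
  d <- delay_design()
  set.seed(21)
  rec <- simulate_choices(d, "beta_delta", beta = 1, delta = 0.97, temperature = 2)
  ll_bd <- oracle_choice_loglik(rec, "beta_delta",
                                c(beta = 1, delta = 0.97, temperature = 2))
  ll_ex <- oracle_choice_loglik(rec, "exponential",
                                c(delta = 0.97, temperature = 2))
  expect_equal(ll_bd, ll_ex, tolerance = 1e-12)
})

test_that("the fitted optimum beats every point of an independent coarse lattice", {
  d <- delay_design()
  set.seed(31)
  rec <- simulate_choices(d, "beta_delta", beta = 0.85, delta = 0.985,
                          temperature = 3)
  fit <- fit_discount(rec, "beta_delta")
  lattice <- expand.grid(beta = seq(0.1, 1.5, by = 0.1),
                         delta = seq(0.91, 1, by = 0.01),
                         temperature = c(0.5, 1, 2, 4, 8))
  ll <- apply(lattice, 1, function(p)
    oracle_choice_loglik(rec, "beta_delta",
                         c(beta = p[["beta"]], delta = p[["delta"]],
                           temperature = p[["temperature"]])))
  expect_gte(fit$logLik, max(ll) - 1e-9)
})

test_that("zero-variance responders get flagged boundary estimates, not failures", {
  d <- delay_design()
  rec <- cbind(d$trials, chose_delayed = 1L)
  fit <- fit_discount(rec, "beta_delta")
  expect_false(fit$converged)
  expect_true(fit$degenerate)
  expect_equal(fit$fit_r2, 0)
  # ML pushes towards maximal delayed utility: both parameters at the top
  expect_equal(unname(coef(fit)[["beta"]]), 1.5)
  expect_equal(unname(coef(fit)[["delta"]]), 1.0)
  # too few records is an error, not a silent fit
  expect_error(fit_discount(rec[1:5, ], "beta_delta"), "at least 8")
  expect_error(fit_discount(rec[1:3, ], "exponential"), "at least 4")
})

test_that("simulated subjects are recovered and recovery sharpens with more trials", {
  d <- delay_design()
  many <- d$trials[rep(seq_len(24), 4), ]  # 96-trial replication
  set.seed(41)
  err24 <- numeric(60); err96 <- numeric(60)
  beta_hat <- numeric(60)
  for (i in 1:60) {
    r24 <- simulate_choices(d, "beta_delta", beta = 0.89, delta = 0.99,
                            temperature = 2)
    r96 <- simulate_choices(many, "beta_delta", beta = 0.89, delta = 0.99,
                            temperature = 2)
    f24 <- fit_discount(r24, "beta_delta")
    f96 <- fit_discount(r96, "beta_delta")
    beta_hat[i] <- coef(f24)[["beta"]]
    err24[i] <- abs(coef(f24)[["beta"]] - 0.89)
    err96[i] <- abs(coef(f96)[["beta"]] - 0.89)
  }
  expect_lt(abs(median(beta_hat) - 0.89), 0.1)
  expect_lte(median(err96), median(err24))
})

test_that("the generating model family wins the per-subject fit comparison", {
  d <- delay_design()
  set.seed(51)
  wins <- logical(40)
  for (i in 1:40) {
    rec <- simulate_choices(d, "beta_delta", beta = 0.8, delta = 0.995,
                            temperature = 2)
    fb <- fit_discount(rec, "beta_delta")
    fh <- fit_discount(rec, "hyperbolic")
    wins[i] <- fh$fit_r2 <= fb$fit_r2
  }
  expect_gte(mean(wins), 0.8)
})

test_that("model comparison nests correctly and rejects empty cohorts", {
  d <- delay_design()
  set.seed(61)
  choices <- do.call(rbind, lapply(1:30, function(i)
    cbind(participant_id = sprintf("S%02d", i), task_id = "delay_discounting",
          simulate_choices(d, "beta_delta", beta = 1, delta = 0.975,
                           temperature = 2))))
  cmp <- compare_discount_models(choices, models = c("beta_delta", "exponential"))
  s <- cmp$summary
  gap <- abs(s$mean_fit_r2[s$model == "beta_delta"] -
             s$mean_fit_r2[s$model == "exponential"])
  expect_lt(gap, 0.02)  # beta-delta contains the exponential at beta = 1
  expect_error(compare_discount_models(data.frame()), "empty cohort")
})

test_that("choice tables round-trip through the long CSV dialect", {
  d <- delay_design()
  set.seed(71)
  ch <- cbind(participant_id = "P1", task_id = "delay_discounting",
              simulate_choices(d, "beta_delta", beta = 0.9, delta = 0.99,
                               temperature = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_choices(ch, f)
  back <- read_choices(f)
  expect_equal(back$chose_delayed, ch$chose_delayed)
  expect_equal(back$delay_days, ch$delay_days)
})
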