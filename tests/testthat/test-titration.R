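test_that("loss-task switching reproduces the canonical gain-100 reading", {
  des <- loss_design()
  resp <- data.frame(gain_amount = des$trials$gain_amount,
                     accepted_gamble = des$trials$gain_amount >= 100)
  r <- estimate_switch(resp, des)
  expect_equal(r$switch_level, 100)
  expect_equal(r$indifference_ratio, 2.0)
  expect_equal(loss_aversion_ratio(r, des), 2.0)
  expect_equal(r$classification, "averse")
  expect_equal(r$n_reversals, 1L)
})

test_that("boundary responders are classified, not dropped", {
  des <- loss_design()
  all_in <- data.frame(gain_amount = des$trials$gain_amount, accepted_gamble = TRUE)
  r <- estimate_switch(all_in, des)
  expect_equal(r$classification, "seeking")
  expect_equal(r$boundary, "lower")
  expect_equal(r$switch_level, 55)
  expect_equal(loss_aversion_ratio(r, des), 1.1)
  none <- data.frame(gain_amount = des$trials$gain_amount, accepted_gamble = FALSE)
  r2 <- estimate_switch(none, des)
  expect_equal(r2$classification, "degenerate")
  expect_equal(loss_aversion_ratio(r2, des), 3.9)
})

test_that("risk-task switching encodes neutrality at the expected value", {
  des <- risk_design()
  sv <- des$trials$safe_amount
  neutral <- data.frame(safe_amount = sv, accepted_gamble = sv < 150)
  r <- estimate_switch(neutral, des)
  expect_equal(r$switch_level, 150)
  expect_equal(risk_ratio(r, des), 2.0)
  expect_equal(r$classification, "neutral")
  averse <- data.frame(safe_amount = sv, accepted_gamble = sv < 90)
  ra <- estimate_switch(averse, des)
  expect_equal(ra$switch_level, 90)
  expect_equal(risk_ratio(ra, des), 300 / 90)
  expect_equal(ra$classification, "averse")
  never <- data.frame(safe_amount = sv, accepted_gamble = FALSE)
  rn <- estimate_switch(never, des)
  expect_equal(rn$switch_level, 10)
  expect_equal(risk_ratio(rn, des), 30)
  expect_equal(rn$classification, "averse")
  expect_equal(rn$boundary, "lower")
  seek <- data.frame(safe_amount = sv, accepted_gamble = sv < 175)
  expect_equal(estimate_switch(seek, des)$classification, "seeking")
})

test_that("a safe amount of zero yields the degenerate sentinel", {
  des0 <- risk_design(safe_from = 0)
  sv <- des0$trials$safe_amount
  odd <- data.frame(safe_amount = sv, accepted_gamble = FALSE)
  r <- estimate_switch(odd, des0)
  expect_equal(r$switch_level, 0)
  expect_equal(r$classification, "degenerate")
  expect_equal(risk_ratio(r, des0), Inf)
})

test_that("the count-based estimator matches a monotone responder with the same acceptances", {
  des <- loss_design()
  g <- sort(des$trials$gain_amount)
  n <- length(g)
  alt <- rep_len(c(0L, 1L), n)         # non-monotone, alternating
  alt[n] <- 1L
  n_acc <- sum(alt)
  mono <- c(rep(0L, n - n_acc), rep(1L, n_acc))
  r_alt <- estimate_switch(data.frame(gain_amount = g, accepted_gamble = alt), des)
  r_mono <- estimate_switch(data.frame(gain_amount = g, accepted_gamble = mono), des)
  expect_equal(r_alt$switch_level, r_mono$switch_level)
  expect_gt(r_alt$n_reversals, r_mono$n_reversals)
})

test_that("estimates are invariant to presentation order", {
  des <- risk_design()
  set.seed(5)
  for (i in 1:10) {
    acc <- as.integer(stats::runif(19) < 0.5)
    base <- data.frame(safe_amount = des$trials$safe_amount, accepted_gamble = acc)
    r0 <- estimate_switch(base, des)
    perm <- sample(19)
    r1 <- estimate_switch(base[perm, ], des)
    expect_equal(r1$switch_level, r0$switch_level)
    expect_equal(r1$n_reversals, r0$n_reversals)
  }
})

test_that("one extra acceptance can only move the switch towards the gamble", {
  des <- loss_design()
  g <- sort(des$trials$gain_amount)
  set.seed(6)
  for (i in 1:20) {
    acc <- as.integer(stats::runif(29) < 0.5)
    if (all(acc == 1)) acc[1] <- 0L
    r0 <- estimate_switch(data.frame(gain_amount = g, accepted_gamble = acc), des)
    j <- sample(which(acc == 0), 1)
    acc2 <- acc; acc2[j] <- 1L
    r1 <- estimate_switch(data.frame(gain_amount = g, accepted_gamble = acc2), des)
    expect_lte(r1$switch_level, r0$switch_level)
  }
})

test_that("incomplete series raise an error naming the missing levels", {
  des <- loss_design()
  resp <- data.frame(gain_amount = des$trials$gain_amount,
                     accepted_gamble = TRUE)[-c(3, 7), ]
  expect_error(estimate_switch(resp, des), "missing level.*65.*85")
})

test_that("cohort-level estimation and the CSV dialect work together", {
  des <- loss_design()
  set.seed(7)
  long <- do.call(rbind, lapply(1:5, function(i)
    cbind(participant_id = sprintf("P%d", i),
          simulate_titration(des, threshold = 60 + 20 * i, lapse = 0))))
  out <- estimate_switch_cohort(long, des)
  expect_equal(nrow(out), 5L)
  expect_equal(out$switch_level, 60 + 20 * (1:5))
  f <- withr::local_tempfile(fileext = ".csv")
  long2 <- data.frame(participant_id = long$participant_id, task_id = "loss",
                      trial_index = long$trial_index,
                      variable_amount = long$gain_amount,
                      fixed_stake = long$loss_amount,
                      accepted_gamble = long$accepted_gamble)
  write_titration(long2, f)
  back <- read_titration(f)
  out2 <- estimate_switch_cohort(back, des)
  expect_equal(out2$switch_level, out$switch_level)
})
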