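small_cfg <- function(n = 60, ninc = 5, seed = 101, ...) {
  cohort_config(n_participants = n, n_incomplete = ninc, seed = seed, ...)
}

test_that("exclusion accounting: incomplete respondents are flagged exactly", {
  ch <- simulate_cohort(small_cfg(), detail = "participants")
  expect_equal(nrow(ch$participants), 60L)
  expect_equal(sum(!ch$participants$complete), 5L)
  full <- simulate_cohort(small_cfg(n = 40, ninc = 6), detail = "full")
  inc_ids <- full$participants$participant_id[!full$participants$complete]
  na_ids <- unique(full$item_responses$participant_id[is.na(full$item_responses$response)])
  expect_setequal(na_ids, inc_ids)   # every incomplete respondent has blanked items
  expect_error(cohort_config(n_participants = 10, n_incomplete = 10),
               "smaller")
})

test_that("identical seeds reproduce the cohort byte for byte; seeds matter", {
  cfg <- small_cfg(n = 30, ninc = 3, seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_cohort(simulate_cohort(cfg), d1)
  f2 <- write_cohort(simulate_cohort(cfg), d2)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
  other <- simulate_cohort(small_cfg(n = 30, ninc = 3, seed = 8))
  expect_false(identical(other$participants$age,
                         simulate_cohort(cfg)$participants$age))
})

test_that("participant-level draws are shared across detail modes", {
  cfg <- small_cfg(n = 25, ninc = 2, seed = 9)
  p1 <- simulate_cohort(cfg, detail = "participants")$participants
  p2 <- simulate_cohort(cfg, detail = "full")$participants
  expect_identical(p1, p2)
})

test_that("a null effect structure leaves traits and outcomes uncorrelated", {
  null_eff <- lapply(default_effect_spec(), function(b) b * 0)
  cfg <- cohort_config(n_participants = 10000, n_incomplete = 0, seed = 11,
                       effects = null_eff)
  p <- simulate_cohort(cfg, detail = "participants")$participants
  for (tr in c("lcb", "mfq_authority", "tci_harm_avoidance", "dd_beta"))
    for (oc in c("perceived_risk", "times_left_home", "likelihood_leisure"))
      expect_lt(abs(cor(p[[tr]], p[[oc]])), 0.05)
})

test_that("the count outcome hits its mean target and is right-skewed", {
  p <- simulate_cohort(cohort_config(n_participants = 10000, n_incomplete = 0,
                                     seed = 12),
                       detail = "participants")$participants
  tlh <- p$times_left_home
  expect_equal(mean(tlh), 2.05, tolerance = 0.05)        # within +/- 5%
  expect_true(all(tlh >= 0 & tlh == round(tlh)))
  skew <- mean((tlh - mean(tlh))^3) / sd(tlh)^3
  expect_gt(skew, 0)
  expect_gt(mean(tlh == 0), 0.2)                         # zero-clustered
  expect_true(all(p$age >= 18 & p$age <= 82))
  expect_true(all(p$perceived_risk >= 1 & p$perceived_risk <= 10))
  expect_true(all(p$likelihood_physical >= 0 & p$likelihood_physical <= 100))
})

test_that("latent traits and scored items are calibrated to their targets", {
  cfg <- cohort_config(n_participants = 10000, n_incomplete = 0, seed = 13)
  ch <- simulate_cohort(cfg, detail = "full")
  tt <- cfg$traits
  lat <- ch$participants
  for (i in seq_len(nrow(tt))) {
    col <- paste(tt$instrument[i], tt$subscale[i], sep = "_")
    expect_lt(abs(mean(lat[[col]]) / tt$mean[i] - 1), 0.03)
    expect_lt(abs(sd(lat[[col]]) / tt$sd[i] - 1), 0.03)
  }
  expect_lt(abs(mean(lat$lcb) / -6.20 - 1), 0.03)
  expect_lt(abs(sd(lat$lcb) / 5.71 - 1), 0.03)
  # item-level reliability within +/- 0.05 of each alpha target
  sc <- score_scales(ch$item_responses, cfg$scales)
  for (i in seq_len(nrow(tt))) {
    def <- cfg$scales[[tt$instrument[i]]]
    items <- def$subscales[[tt$subscale[i]]]
    m <- items_wide(ch$item_responses, items, def$item_range, def$reverse_keyed)
    expect_lt(abs(cronbach_alpha(m) - tt$alpha[i]), 0.05)
    # observed score means track the targets (sds attenuate by discretization)
    col <- paste(tt$instrument[i], tt$subscale[i], sep = "_")
    expect_lt(abs(mean(sc[[col]]) / tt$mean[i] - 1), 0.03)
    expect_lt(abs(sd(sc[[col]]) / tt$sd[i] - 1), 0.12)
  }
})

test_that("the recovery loop closes: titration thresholds come back exactly", {
  ec <- cohort_config()$econ; ec$lapse <- 0
  cfg <- cohort_config(n_participants = 300, n_incomplete = 0, seed = 14,
                       econ = ec)
  ch <- simulate_cohort(cfg, "full")
  truth <- true_parameter_table(ch)
  sw_loss <- estimate_switch_cohort(ch$titration[ch$titration$task_id == "loss", ],
                                    ch$designs$loss)
  sw_risk <- estimate_switch_cohort(ch$titration[ch$titration$task_id == "risk", ],
                                    ch$designs$risk)
  expect_equal(sw_loss$switch_level,
               truth$loss_switch_level[match(sw_loss$participant_id,
                                             truth$participant_id)])
  expect_equal(sw_risk$switch_level,
               truth$risk_switch_level[match(sw_risk$participant_id,
                                             truth$participant_id)])
})

test_that("the true-parameter table is complete, deterministic and seed-sensitive", {
  cfg <- small_cfg(n = 20, ninc = 0, seed = 15)
  t1 <- true_parameter_table(simulate_cohort(cfg, "participants"))
  t2 <- true_parameter_table(simulate_cohort(cfg, "participants"))
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 20L)
  expect_true(all(c("dd_beta", "dd_delta", "loss_threshold", "risk_threshold",
                    "lcb", "mfq_authority") %in% names(t1)))
  expect_named(attr(t1, "effects"), names(default_effect_spec()))
  t3 <- true_parameter_table(
    simulate_cohort(small_cfg(n = 20, ninc = 0, seed = 16), "participants"))
  expect_false(identical(t1$dd_beta, t3$dd_beta))
})

test_that("a non-positive-definite trait correlation is rejected", {
  expect_error(simulate_cohort(small_cfg(trait_cor = list(within = -0.9,
                                                          between = -0.9))),
               "positive definite")
})
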