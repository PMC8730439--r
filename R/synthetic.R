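#' Configuration for the synthetic survey cohort
#'
#' Bundles every generating assumption of the simulated study: sample
#' size and number of incomplete respondents, demographic distributions,
#' latent trait means/sds with an exchangeable correlation structure,
#' per-subscale reliability targets for the one-factor item model,
#' psycho-economic parameter distributions, the four compliance outcomes
#' (an approximately normal 1-10 risk rating and three right-skewed,
#' zero-clustered quantities drawn from a Tweedie distribution on a log
#' link), and the standardized effect coefficients linking traits to
#' outcomes. Defaults reproduce the descriptive structure of the study
#' cohort the package emulates: 269 respondents of whom 25 are incomplete
#' (244 analysable), 68.86% female, age 33.04 +/- 13.54 within 18-82,
#' education 16.36 +/- 2.65 years, the trait means/sds and reliabilities
#' listed in [default_trait_table()], median-0.89 present bias and
#' median-0.99 daily discount factor, a loss-aversion threshold near a
#' gain/loss ratio of 2, and outcome means/sds of 2.05/3.86 (times left
#' home), 4.48/2.11 (perceived risk), 10.29/22.61 and 4.06/14.51 (the two
#' leave-home likelihoods).
#'
#' @param n_participants cohort size before exclusions.
#' @param n_incomplete number of respondents flagged incomplete (at least
#'   one blanked item); must be smaller than `n_participants`.
#' @param seed integer RNG seed; every draw derives from it.
#' @param traits data frame as [default_trait_table()]: one latent trait
#'   per subscale with target mean/sd and reliability (alpha) target.
#' @param trait_cor list with elements `within` and `between`:
#'   exchangeable correlations within and between instruments. The
#'   internal/external locus pair is left uncorrelated so the
#'   difference-score sd matches its target.
#' @param demographics list: `p_female`, `age_mean`, `age_sd`, `age_range`,
#'   `edu_mean`, `edu_sd`, `edu_range`.
#' @param econ list of psycho-economic generating parameters: `beta_mean`,
#'   `beta_sd`, `delta_mean`, `delta_sd`, `temperature`, `loss_switch_mean`,
#'   `loss_switch_sd`, `risk_switch_mean`, `risk_switch_sd`, `lapse`.
#' @param outcomes list per outcome with `mean`, `sd` (and `range` where
#'   bounded).
#' @param effects named list per outcome of named standardized
#'   coefficients; see [default_effect_spec()].
#' @param r_squared named vector of target model R-squared values, used to
#'   set the residual noise scale of the linear predictors.
#' @param tweedie_power Tweedie variance power in (1, 2); default 1.5.
#' @param scales scale definitions used to shape item responses.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 269,
                          n_incomplete = 25,
                          seed = 20200330,
                          traits = default_trait_table(),
                          trait_cor = list(within = 0.2, between = 0.1),
                          demographics = list(p_female = 0.6886,
                                              age_mean = 33.04, age_sd = 13.54,
                                              age_range = c(18, 82),
                                              edu_mean = 16.36, edu_sd = 2.65,
                                              edu_range = c(8, 25)),
                          econ = list(beta_mean = 0.89, beta_sd = 0.15,
                                      delta_mean = 0.99, delta_sd = 0.01,
                                      temperature = 2,
                                      loss_switch_mean = 100, loss_switch_sd = 25,
                                      risk_switch_mean = 90, risk_switch_sd = 40,
                                      lapse = 0.05),
                          outcomes = list(
                            perceived_risk = list(mean = 4.48, sd = 2.11, range = c(1, 10)),
                            times_left_home = list(mean = 2.05, sd = 3.86),
                            likelihood_physical = list(mean = 10.29, sd = 22.61, range = c(0, 100)),
                            likelihood_leisure = list(mean = 4.06, sd = 14.51, range = c(0, 100))),
                          effects = default_effect_spec(),
                          r_squared = c(perceived_risk = 0.124,
                                        times_left_home = 0.143,
                                        likelihood_physical = 0.120,
                                        likelihood_leisure = 0.101),
                          tweedie_power = 1.5,
                          scales = default_scale_definitions()) {
  if (n_incomplete >= n_participants)
    stop("n_incomplete must be smaller than n_participants")
  if (tweedie_power <= 1 || tweedie_power >= 2)
    stop("tweedie_power must be in (1, 2)")
  if (any(traits$sd <= 0)) stop("all trait sds must be positive")
  structure(list(n_participants = as.integer(n_participants),
                 n_incomplete = as.integer(n_incomplete),
                 seed = as.integer(seed), traits = traits,
                 trait_cor = trait_cor, demographics = demographics,
                 econ = econ, outcomes = outcomes, effects = effects,
                 r_squared = r_squared, tweedie_power = tweedie_power,
                 scales = scales),
            class = "cohort_config")
}

#' Default latent trait targets
#'
#' One row per subscale: instrument, subscale name, target mean and sd of
#' the observed score (sum-scored for the locus and temperament
#' instruments, mean-scored for the moral foundations), and the target
#' internal-consistency (alpha) of its items. The locus instrument is
#' represented by its internal and external subscales; their difference is
#' the analysis variable (target mean -6.20, sd 5.71, reached by two
#' independent latents with sd 5.71/sqrt(2) each).
#'
#' @return data frame with columns `instrument`, `subscale`, `mean`, `sd`,
#'   `alpha`.
#' @export
default_trait_table <- function() {
  data.frame(
    instrument = c("lcb", "lcb",
                   rep("mfq", 5), rep("tci", 7)),
    subscale = c("internal", "external",
                 "harm", "fairness", "ingroup", "authority", "purity",
                 "harm_avoidance", "novelty_seeking", "reward_dependence",
                 "persistence", "self_directedness", "cooperativeness",
                 "self_transcendence"),
    mean = c(20.0, 26.2,
             3.86, 3.95, 3.01, 2.61, 2.05,
             24.61, 20.27, 28.94, 28.47, 28.75, 31.14, 20.00),
    sd = c(5.71 / sqrt(2), 5.71 / sqrt(2),
           0.63, 0.49, 0.81, 0.79, 0.97,
           5.34, 4.51, 5.94, 4.97, 5.18, 4.66, 7.39),
    alpha = c(0.72, 0.75,
              0.69, 0.63, 0.77, 0.74, 0.83,
              0.75, 0.73, 0.77, 0.76, 0.75, 0.76, 0.78)
  )
}

#' Default standardized effect coefficients per outcome
#'
#' The generating effect structure: standardized coefficients of each
#' z-scored predictor in the linear predictor of each outcome (log-scale
#' for the three Tweedie outcomes). Predictors with no reported effect are
#' 0. `gender` codes female = 1.
#'
#' @return named list per outcome of named coefficient vectors.
#' @export
default_effect_spec <- function() {
  list(
    perceived_risk = c(gender = 0.141, tci_harm_avoidance = 0.129),
    times_left_home = c(age = 0.267, lcb = -0.238, mfq_authority = -0.167),
    likelihood_physical = c(lcb = -0.137, mfq_authority = -0.131,
                            tci_harm_avoidance = -0.132,
                            loss_aversion = -0.157,
                            dd_beta = 0.141, dd_delta = -0.239),
    likelihood_leisure = c(lcb = -0.123, tci_harm_avoidance = -0.141,
                           dd_beta = 0.163, dd_delta = -0.284)
  )
}

rtruncnorm_q <- function(n, mean, sd, lower, upper) {
  # inverse-CDF truncation: deterministic given the RNG stream
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

build_trait_sigma <- function(traits, trait_cor) {
  p <- nrow(traits)
  S <- matrix(trait_cor$between, p, p)
  for (ins in unique(traits$instrument)) {
    idx <- which(traits$instrument == ins)
    S[idx, idx] <- trait_cor$within
  }
  diag(S) <- 1
  # keep the locus difference-score sd on target: int/ext uncorrelated
  lcb <- which(traits$instrument == "lcb")
  if (length(lcb) == 2) { S[lcb[1], lcb[2]] <- 0; S[lcb[2], lcb[1]] <- 0 }
  S
}

# Inter-item correlation implied by an alpha target for k parallel items,
# inflated to compensate for the attenuation introduced by discretizing
# items to the integer response grid (round + clamp loses ~8% of the
# inter-item correlation for a 0-5 grid at these item variances).
DISCRETIZATION_COMP <- 1.09

latent_interitem_r <- function(alpha, k) {
  r <- alpha / (k - (k - 1) * alpha)
  min(0.97, r * DISCRETIZATION_COMP)
}

# Generate discretized one-factor item responses for one subscale.
# trait_z: latent standard-normal trait value per participant.
subscale_items <- function(trait_z, items, target_mean, target_sd, alpha,
                           aggregate, item_range) {
  n <- length(trait_z); k <- length(items)
  r <- latent_interitem_r(alpha, k)
  lambda <- sqrt(r)
  item_var <- if (aggregate == "sum") target_sd^2 / (k * (1 + (k - 1) * r))
              else target_sd^2 * k / (1 + (k - 1) * r)
  item_mean <- if (aggregate == "sum") target_mean / k else target_mean
  eps <- matrix(stats::rnorm(n * k), n, k)
  x <- item_mean + sqrt(item_var) * (lambda * trait_z + sqrt(1 - lambda^2) * eps)
  x <- round(x)
  x[x < item_range[1]] <- item_range[1]
  x[x > item_range[2]] <- item_range[2]
  colnames(x) <- items
  x
}

#' Generate a synthetic survey cohort
#'
#' Draws a full cohort from a [cohort_config()]: demographics
#' (truncated-normal age and education, Bernoulli gender, categorical
#' occupation/housing), multivariate-normal latent traits with the
#' configured exchangeable correlation structure, discretized one-factor
#' item responses calibrated to the per-subscale reliability targets,
#' psycho-economic parameters (truncated-normal present bias, discount
#' factor and titration thresholds), task responses (binary intertemporal
#' choices via the logistic choice rule; deterministic titration
#' thresholds plus lapse noise), and the four compliance outcomes — the
#' risk rating as a rescaled Gaussian and the three zero-clustered
#' quantities as Tweedie draws whose log-scale linear predictor carries the
#' configured standardized effects, with dispersion set from the target
#' sds and the mean calibrated so the sample outcome mean matches its
#' target. Exactly `n_incomplete` respondents get 1-3 blanked items and
#' `complete = FALSE`. Everything derives from `config$seed`: the same
#' config reproduces the cohort byte for byte.
#'
#' @param config a [cohort_config()].
#' @param detail `"full"` (item + task responses included) or
#'   `"participants"` (participant-level table only; identical draws for
#'   the shared columns).
#' @return An object of class `psyecon_cohort`: `participants` (wide table
#'   of demographics, latent traits, psycho-economic parameters and
#'   outcomes), `item_responses`, `choices`, `titration` (long tables;
#'   `NULL` under `detail = "participants"`), `designs`, and the `config`.
#' @examples
#' ch <- simulate_cohort(cohort_config(n_participants = 40, n_incomplete = 4,
#'                                     seed = 1), detail = "participants")
#' nrow(ch$participants)
#' @export
simulate_cohort <- function(config = cohort_config(),
                            detail = c("full", "participants")) {
  stopifnot(inherits(config, "cohort_config"))
  detail <- match.arg(detail)
  set.seed(config$seed)
  n <- config$n_participants
  dm <- config$demographics
  ec <- config$econ
  traits <- config$traits

  ids <- sprintf("P%04d", seq_len(n))
  gender <- ifelse(stats::runif(n) < dm$p_female, "female", "male")
  age <- round(rtruncnorm_q(n, dm$age_mean, dm$age_sd,
                            dm$age_range[1], dm$age_range[2]))
  education <- round(rtruncnorm_q(n, dm$edu_mean, dm$edu_sd,
                                  dm$edu_range[1], dm$edu_range[2]))
  occupation <- sample(c("student", "unemployed", "freelancer", "employee",
                         "worker", "retired", "healthcare", "researcher",
                         "seller", "agriculture", "other"),
                       n, replace = TRUE,
                       prob = c(0.3606, 0.0204, 0.0983, 0.168, 0.0081,
                                0.0573, 0.0655, 0.0983, 0.0081, 0.004, 0.1114))
  housing <- sample(c("alone", "housemate", "partner", "children",
                      "parents_siblings"),
                    n, replace = TRUE,
                    prob = c(0.127, 0.1106, 0.3852, 0.168, 0.2092))

  S <- build_trait_sigma(traits, config$trait_cor)
  L <- tryCatch(chol(S), error = function(e)
    stop("trait correlation matrix is not positive definite"))
  Zt <- matrix(stats::rnorm(n * nrow(traits)), n) %*% L
  trait_names <- paste(traits$instrument, traits$subscale, sep = "_")
  colnames(Zt) <- trait_names
  trait_vals <- sweep(sweep(Zt, 2, traits$sd, "*"), 2, traits$mean, "+")

  dd_beta <- rtruncnorm_q(n, ec$beta_mean, ec$beta_sd, 0.05, 1.5)
  dd_delta <- rtruncnorm_q(n, ec$delta_mean, ec$delta_sd, 0.905, 1.0)
  # thresholds truncated to the titration grids so that the grid switch
  # level implied by a lapse-free responder is always defined
  loss_thr <- rtruncnorm_q(n, ec$loss_switch_mean, ec$loss_switch_sd, 51, 195)
  risk_thr <- rtruncnorm_q(n, ec$risk_switch_mean, ec$risk_switch_sd, 11, 190)

  designs <- list(delay = delay_design(), risk = risk_design(), loss = loss_design())
  loss_levels <- sort(designs$loss$trials$gain_amount)
  risk_levels <- sort(designs$risk$trials$safe_amount)
  snap_up <- function(thr, levels) {
    i <- findInterval(thr, levels, left.open = TRUE) + 1L
    ifelse(i > length(levels), NA_real_, levels[i])
  }
  # grid switch level implied by the latent threshold (lapse-free)
  loss_switch <- ifelse(loss_thr <= loss_levels[1], loss_levels[1],
                        snap_up(loss_thr, loss_levels))
  risk_switch <- ifelse(risk_thr <= risk_levels[1], risk_levels[1],
                        snap_up(risk_thr, risk_levels))
  loss_aversion <- loss_thr / designs$loss$trials$loss_amount[1]
  risk_aversion <- designs$risk$trials$lottery_amount[1] / risk_thr

  part <- data.frame(participant_id = ids, complete = TRUE,
                     gender = gender, age = age, education = education,
                     occupation = occupation, housing = housing,
                     stringsAsFactors = FALSE)
  part <- cbind(part, as.data.frame(trait_vals))
  part$lcb <- part$lcb_internal - part$lcb_external
  part$dd_beta <- dd_beta
  part$dd_delta <- dd_delta
  part$dd_temperature <- ec$temperature
  part$loss_threshold <- loss_thr
  part$risk_threshold <- risk_thr
  part$loss_switch_level <- loss_switch
  part$risk_switch_level <- risk_switch
  part$loss_aversion <- loss_aversion
  part$risk_aversion <- risk_aversion

  # outcomes: standardized linear predictor from z-scored generating values
  zcol <- function(v) (v - mean(v)) / stats::sd(v)
  pred_z <- list(gender = zcol(as.numeric(gender == "female")),
                 age = zcol(age), education = zcol(education),
                 lcb = zcol(part$lcb),
                 mfq_authority = zcol(part$mfq_authority),
                 tci_harm_avoidance = zcol(part$tci_harm_avoidance),
                 tci_novelty_seeking = zcol(part$tci_novelty_seeking),
                 dd_beta = zcol(dd_beta), dd_delta = zcol(dd_delta),
                 loss_aversion = zcol(loss_aversion),
                 risk_aversion = zcol(risk_aversion))
  eta_for <- function(outcome) {
    b <- config$effects[[outcome]]
    eta <- numeric(n)
    for (nm in names(b)) {
      if (is.null(pred_z[[nm]])) stop("effect names unknown predictor: ", nm)
      eta <- eta + b[[nm]] * pred_z[[nm]]
    }
    eta
  }

  oc <- config$outcomes
  r2 <- config$r_squared
  # 1-10 risk rating: Gaussian on the standardized scale, rescaled, rounded
  eta_pr <- eta_for("perceived_risk")
  noise_sd <- sqrt(max(0.05, 1 - r2[["perceived_risk"]]))
  pr <- oc$perceived_risk$mean +
    oc$perceived_risk$sd * (eta_pr + stats::rnorm(n, 0, noise_sd))
  pr <- round(pmin(pmax(pr, oc$perceived_risk$range[1]), oc$perceived_risk$range[2]))
  part$perceived_risk <- pr

  tweedie_outcome <- function(outcome, integer_valued = FALSE) {
    spec <- oc[[outcome]]
    # On the log link a standardized coefficient b attenuates to a linear
    # (OLS) standardized effect of roughly b * mean/sd; scaling the linear
    # predictor by sd/mean makes the OLS stage recover the configured
    # standardized coefficients while the log-scale (Tweedie) coefficients
    # land at b * sd/mean — the relation the emulated effect tables obey.
    eta <- eta_for(outcome) * spec$sd / spec$mean
    mu <- exp(eta)
    mu <- spec$mean * mu / mean(mu)            # sample-mean calibration
    p <- config$tweedie_power
    phi <- max((spec$sd^2 - stats::var(mu)) / mean(mu^p), 0.1)
    y <- rtweedie_cp(n, mu, phi, p)
    if (!is.null(spec$range)) y <- pmin(pmax(y, spec$range[1]), spec$range[2])
    if (integer_valued) y <- round(y)
    y
  }
  part$times_left_home <- tweedie_outcome("times_left_home", integer_valued = TRUE)
  part$likelihood_physical <- tweedie_outcome("likelihood_physical")
  part$likelihood_leisure <- tweedie_outcome("likelihood_leisure")

  incomplete_ids <- sample(ids, config$n_incomplete)
  part$complete[part$participant_id %in% incomplete_ids] <- FALSE

  item_responses <- NULL; choices <- NULL; titration <- NULL
  if (detail == "full") {
    # item responses per subscale, direct-keyed then reflected for stored form
    item_blocks <- vector("list", nrow(traits))
    for (i in seq_len(nrow(traits))) {
      def <- config$scales[[traits$instrument[i]]]
      items <- def$subscales[[traits$subscale[i]]]
      x <- subscale_items(Zt[, i], items, traits$mean[i], traits$sd[i],
                          traits$alpha[i], def$aggregate, def$item_range)
      rev_items <- intersect(def$reverse_keyed, items)
      if (length(rev_items))
        x[, rev_items] <- def$item_range[1] + def$item_range[2] - x[, rev_items]
      item_blocks[[i]] <- data.frame(
        participant_id = rep(ids, times = ncol(x)),
        scale_id = def$scale_id,
        item_id = rep(colnames(x), each = n),
        response = as.vector(x))
    }
    item_responses <- do.call(rbind, item_blocks)
    item_responses <- item_responses[order(item_responses$participant_id,
                                           item_responses$item_id), ]
    rownames(item_responses) <- NULL
    # blank 1-3 items per incomplete respondent
    for (id in incomplete_ids) {
      rows <- which(item_responses$participant_id == id)
      k <- sample(1:3, 1)
      item_responses$response[sample(rows, k)] <- NA
    }

    # choice probabilities for all participants x trials at once
    tr <- designs$delay$trials
    nt <- nrow(tr)
    u_del <- outer(dd_beta * 1, tr$delayed_amount) *
      outer(dd_delta, tr$delay_days, "^")
    pmat <- stats::plogis(sweep(u_del, 2, tr$immediate_amount, "-") /
                            ec$temperature)
    chose <- matrix(stats::runif(n * nt), n, nt) < pmat
    choices <- data.frame(
      participant_id = rep(ids, each = nt),
      task_id = "delay_discounting",
      trial_index = rep(tr$trial_index, times = n),
      immediate_amount = rep(tr$immediate_amount, times = n),
      delayed_amount = rep(tr$delayed_amount, times = n),
      delay_days = rep(tr$delay_days, times = n),
      chose_delayed = as.integer(t(chose)))

    titr <- function(design, thr_vec, vcol, fixed_col) {
      trd <- design$trials
      k <- nrow(trd)
      v <- trd[[vcol]]
      acc <- if (design$task_id == "loss") outer(thr_vec, v, function(t, g) g >= t)
             else outer(thr_vec, v, function(t, s) s < t)
      if (ec$lapse > 0)
        acc <- xor(acc, matrix(stats::runif(n * k) < ec$lapse, n, k))
      data.frame(participant_id = rep(ids, each = k),
                 task_id = design$task_id,
                 trial_index = rep(trd$trial_index, times = n),
                 variable_amount = rep(v, times = n),
                 fixed_stake = rep(trd[[fixed_col]], times = n),
                 accepted_gamble = as.integer(t(acc)))
    }
    titration <- rbind(titr(designs$loss, loss_thr, "gain_amount", "loss_amount"),
                       titr(designs$risk, risk_thr, "safe_amount", "lottery_amount"))
    rownames(titration) <- NULL
  }

  structure(list(participants = part, item_responses = item_responses,
                 choices = choices, titration = titration,
                 designs = designs, config = config),
            class = "psyecon_cohort")
}

#' @export
print.psyecon_cohort <- function(x, ...) {
  p <- x$participants
  cat(sprintf("Synthetic cohort: %d participants (%d complete), seed %d\n",
              nrow(p), sum(p$complete), x$config$seed))
  if (!is.null(x$item_responses))
    cat(sprintf("  %d item responses, %d choices, %d titration responses\n",
                nrow(x$item_responses), nrow(x$choices), nrow(x$titration)))
  invisible(x)
}

#' Table of every latent generating value
#'
#' One row per participant with the latent traits, discounting parameters,
#' titration thresholds and implied grid switch levels; the generating
#' effect coefficients are attached as the `"effects"` attribute. Intended
#' for parameter-recovery tests.
#'
#' @param cohort a `psyecon_cohort`.
#' @return data frame with attribute `effects`.
#' @export
true_parameter_table <- function(cohort) {
  stopifnot(inherits(cohort, "psyecon_cohort"))
  p <- cohort$participants
  latent_cols <- c("participant_id",
                   paste(cohort$config$traits$instrument,
                         cohort$config$traits$subscale, sep = "_"),
                   "lcb", "dd_beta", "dd_delta", "dd_temperature",
                   "loss_threshold", "risk_threshold",
                   "loss_switch_level", "risk_switch_level",
                   "loss_aversion", "risk_aversion")
  out <- p[, latent_cols]
  attr(out, "effects") <- cohort$config$effects
  out
}

#' Write cohort tables to CSV files
#'
#' Emits the CSV dialects the analysis stages consume: `participants.csv`,
#' `item_responses.csv`, `choices.csv`, `titration.csv`, and one design
#' file per task.
#'
#' @param cohort a `psyecon_cohort`.
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    files <<- c(files, f)
  }
  wr(cohort$participants, "participants.csv")
  if (!is.null(cohort$item_responses)) wr(cohort$item_responses, "item_responses.csv")
  if (!is.null(cohort$choices)) wr(cohort$choices, "choices.csv")
  if (!is.null(cohort$titration)) wr(cohort$titration, "titration.csv")
  for (nm in names(cohort$designs)) {
    f <- file.path(dir, sprintf("design_%s.csv", nm))
    write_design(cohort$designs[[nm]], f)
    files <- c(files, f)
  }
  invisible(files)
}
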