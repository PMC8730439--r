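#' Switching-point estimation for titrated gamble series
#'
#' Estimates the preference switching point from responses to a monotone
#' series of offers (the risk lottery or the mixed-gamble loss series).
#' The estimator is count-based: responses are sorted by the variable
#' amount and the switch level is the level at which the subject's
#' acceptance count places the switch — for a perfectly monotone responder
#' this is exactly the single reversal point, and for noisy responders it
#' is robust to isolated reversals (a responder with the same number of
#' acceptances always gets the same switch level, however the acceptances
#' are arranged). The estimate is therefore invariant to presentation
#' order. `n_reversals` counts adjacent preference changes along the
#' sorted series (1 for a clean monotone switch; more indicates noise).
#'
#' Conventions per task:
#' \describe{
#'   \item{loss}{gains ascend; the expected pattern is reject -> accept and
#'     the switch level is the first *accepted* gain. Any rejection of a
#'     positive-expected-value gamble marks loss aversion; a responder
#'     accepting everything is classified `seeking` (switch at the lower
#'     grid bound), one rejecting everything `degenerate` (upper bound).}
#'   \item{risk}{safe amounts ascend; the expected pattern is accept ->
#'     reject (gamble while the safe amount is small) and the switch level
#'     is the first *safe-preferred* amount. Switching below the lottery's
#'     expected value (150 by default) is `averse`, at it `neutral`, at or
#'     above the next level up `seeking`. A subject who gambles on every
#'     trial switches beyond the grid (`seeking`, upper bound); one who
#'     never gambles switches at the lowest level (`averse`). A switch
#'     level of 0 (only possible when the design includes safe amount 0)
#'     is `degenerate`.}
#' }
#'
#' @param responses data frame covering the full design once, with the
#'   design's variable-amount column (`gain_amount` or `safe_amount`) and
#'   `accepted_gamble` (0/1 or logical). Order is irrelevant.
#' @param design the `task_design` the responses answer.
#' @return An object of class `switch_result` with fields `task_id`,
#'   `switch_level`, `indifference_ratio`, `n_acceptances`, `n_reversals`,
#'   `classification` (averse / neutral / seeking / degenerate) and
#'   `boundary` ("none", "lower", "upper").
#' @examples
#' des <- loss_design()
#' resp <- data.frame(gain_amount = des$trials$gain_amount,
#'                    accepted_gamble = des$trials$gain_amount >= 100)
#' estimate_switch(resp, des)  # switch at 100, ratio 2
#' @export
estimate_switch <- function(responses, design) {
  stopifnot(inherits(design, "task_design"))
  vcol <- design_variable_column(design)
  responses <- as.data.frame(responses)
  if (!vcol %in% names(responses) && "variable_amount" %in% names(responses))
    names(responses)[names(responses) == "variable_amount"] <- vcol
  if (!vcol %in% names(responses))
    stop(sprintf("responses lack the '%s' column", vcol))
  if (!"accepted_gamble" %in% names(responses))
    stop("responses lack the 'accepted_gamble' column")
  levels_design <- sort(design$trials[[vcol]])
  got <- sort(responses[[vcol]])
  if (length(got) != length(levels_design) || any(got != levels_design)) {
    missing_levels <- setdiff(levels_design, responses[[vcol]])
    if (length(missing_levels))
      stop("incomplete titration series; missing level(s): ",
           paste(missing_levels, collapse = ", "))
    stop("titration responses do not match the design's levels one-to-one")
  }
  ord <- order(responses[[vcol]])
  acc <- as.integer(as.logical(responses$accepted_gamble[ord]))
  lev <- responses[[vcol]][ord]
  n <- length(lev)
  n_acc <- sum(acc)
  n_rev <- sum(abs(diff(acc)))

  if (design$task_id == "loss") {
    fixed <- design$trials$loss_amount[1]
    if (n_acc == 0L) {           # rejects even the most favourable gamble
      switch_level <- lev[n]; boundary <- "upper"; class_ <- "degenerate"
    } else if (n_acc == n) {     # accepts everything on offer
      switch_level <- lev[1]; boundary <- "lower"; class_ <- "seeking"
    } else {                     # first accepted gain, counting from the top
      switch_level <- lev[n - n_acc + 1L]; boundary <- "none"; class_ <- "averse"
    }
    ratio <- switch_level / fixed
  } else if (design$task_id == "risk") {
    fixed <- design$trials$lottery_amount[1]
    ev <- fixed * design$trials$win_probability[1]
    if (n_acc == n) {            # gambles on every trial: switch beyond grid
      switch_level <- lev[n]; boundary <- "upper"; class_ <- "seeking"
    } else {                     # first safe-preferred level
      switch_level <- lev[n_acc + 1L]
      boundary <- if (n_acc == 0L) "lower" else "none"
      class_ <- if (switch_level == 0) "degenerate"
                else if (switch_level < ev) "averse"
                else if (switch_level == ev) "neutral"
                else "seeking"
    }
    ratio <- if (switch_level == 0) Inf else fixed / switch_level
  } else stop(sprintf("task '%s' is not a titration task", design$task_id))

  structure(list(task_id = design$task_id,
                 switch_level = switch_level,
                 indifference_ratio = unname(ratio),
                 n_acceptances = n_acc,
                 n_reversals = n_rev,
                 classification = class_,
                 boundary = boundary),
            class = "switch_result")
}

#' @export
print.switch_result <- function(x, ...) {
  cat(sprintf("Titration switch (%s): level %g, ratio %.3f, %s%s; %d reversal(s)\n",
              x$task_id, x$switch_level, x$indifference_ratio, x$classification,
              if (x$boundary != "none") paste0(" [", x$boundary, " boundary]") else "",
              x$n_reversals))
  invisible(x)
}

#' Loss-aversion (gain/loss) ratio of a switch result
#'
#' The individual indifference point expressed as the ratio of the first
#' accepted gain to the fixed loss (50 by default); a ratio near 2 is the
#' canonical loss-aversion value.
#'
#' @param result a `switch_result` from the loss task.
#' @param design the loss `task_design`.
#' @return the dimensionless gain/loss ratio.
#' @examples
#' loss_aversion_ratio(list(task_id = "loss", switch_level = 100), loss_design())
#' @export
loss_aversion_ratio <- function(result, design) {
  stopifnot(design$task_id == "loss")
  if (!identical(result$task_id, "loss")) stop("result is not from the loss task")
  result$switch_level / design$trials$loss_amount[1]
}

#' Risk-aversion (gamble/safe) ratio of a switch result
#'
#' The lottery's fixed sum divided by the safe amount at which the subject
#' abandons the gamble. A risk-neutral agent switches at the lottery's
#' expected value (safe 150 for a 50/50 lottery over 300), giving ratio 2;
#' larger ratios indicate risk aversion. A switch level of 0 yields an
#' infinite (sentinel) ratio.
#'
#' @param result a `switch_result` from the risk task.
#' @param design the risk `task_design`.
#' @return the dimensionless gamble/safe ratio.
#' @export
risk_ratio <- function(result, design) {
  stopifnot(design$task_id == "risk")
  if (!identical(result$task_id, "risk")) stop("result is not from the risk task")
  if (result$switch_level == 0) return(Inf)
  design$trials$lottery_amount[1] / result$switch_level
}

#' Estimate switching points for every participant in a long response table
#'
#' @param responses long table with `participant_id`, the design's
#'   variable-amount column and `accepted_gamble`.
#' @param design the `task_design` answered.
#' @return data frame with one row per participant: switch level, ratio,
#'   acceptance/reversal counts, classification and boundary flag.
#' @export
estimate_switch_cohort <- function(responses, design) {
  stopifnot("participant_id" %in% names(responses))
  ids <- unique(responses$participant_id)
  chunks <- split(responses, factor(responses$participant_id, levels = ids))
  out <- do.call(rbind, lapply(seq_along(ids), function(ii) {
    id <- ids[ii]
    r <- estimate_switch(chunks[[ii]], design)
    data.frame(participant_id = id, task_id = r$task_id,
               switch_level = r$switch_level,
               indifference_ratio = r$indifference_ratio,
               n_acceptances = r$n_acceptances, n_reversals = r$n_reversals,
               classification = r$classification, boundary = r$boundary)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate titration responses from a latent threshold
#'
#' Deterministic threshold responding plus optional lapse noise: the
#' subject accepts the gamble when the offer favours it under their latent
#' threshold (loss task: gain >= threshold; risk task: safe amount <
#' threshold), then each response flips independently with probability
#' `lapse`. Uses the current RNG state.
#'
#' @param design a risk or loss `task_design`.
#' @param threshold latent switching threshold on the variable-amount scale.
#' @param lapse per-trial flip probability in \[0, 0.5).
#' @return the design's trial table plus `accepted_gamble` (0/1).
#' @export
simulate_titration <- function(design, threshold, lapse = 0) {
  stopifnot(lapse >= 0, lapse < 0.5)
  vcol <- design_variable_column(design)
  v <- design$trials[[vcol]]
  acc <- if (design$task_id == "loss") v >= threshold else v < threshold
  if (lapse > 0) {
    flip <- stats::runif(length(acc)) < lapse
    acc <- xor(acc, flip)
  }
  cbind(design$trials, accepted_gamble = as.integer(acc))
}

#' Read/write the long-format titration response CSV dialect
#'
#' Columns: `participant_id`, `task_id`, `trial_index`, `variable_amount`,
#' `fixed_stake`, `accepted_gamble` (0/1).
#'
#' @param responses long-format response table.
#' @param path file path.
#' @export
write_titration <- function(responses, path) {
  cols <- c("participant_id", "task_id", "trial_index", "variable_amount",
            "fixed_stake", "accepted_gamble")
  miss <- setdiff(cols, names(responses))
  if (length(miss)) stop("titration table lacks: ", paste(miss, collapse = ", "))
  utils::write.csv(responses[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
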