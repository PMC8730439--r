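#' Task designs for the psycho-economic elicitation battery
#'
#' Deterministic constructors for the three choice tasks used to elicit
#' delay discounting, risk aversion and loss aversion. Each constructor
#' returns a `task_design` object: a task identifier plus an ordered trial
#' table. Construction is pure — identical arguments always yield an
#' identical trial list — and an optional `shuffle_seed` permutes the
#' presentation order reproducibly without affecting any estimator (all
#' estimators sort the series internally).
#'
#' @name task_designs
#' @keywords internal
NULL

new_task_design <- function(task_id, trials) {
  stopifnot(is.character(task_id), length(task_id) == 1L, is.data.frame(trials))
  trials$trial_index <- seq_len(nrow(trials)) - 1L
  trials <- trials[, c("trial_index", setdiff(names(trials), "trial_index"))]
  structure(list(task_id = task_id, trials = trials), class = "task_design")
}

shuffle_trials <- function(design, shuffle_seed) {
  if (is.null(shuffle_seed)) return(design)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(shuffle_seed))
  perm <- sample.int(nrow(design$trials))
  design$trials <- design$trials[perm, , drop = FALSE]
  design$trials$trial_index <- seq_len(nrow(design$trials)) - 1L
  rownames(design$trials) <- NULL
  design
}

#' Intertemporal (delay-discounting) choice design
#'
#' Builds the 24-trial immediate-vs-delayed reward design: six
#' immediate/delayed amount pairs crossed with four delay durations
#' (7, 30, 60, 90 days). The immediate amounts come from the level set
#' \{50, 55, 70, 90\} and the delayed amounts from \{55, 70, 90, 110\};
#' the default pair subset spans the ratio range of the full crossing while
#' honouring the 24-trial count. Every pair must strictly favour the delayed
#' amount (`delayed > immediate`) so that delayed choice is never dominated
#' by magnitude alone.
#'
#' @param pairs two-column matrix or data frame of (immediate, delayed)
#'   amounts, one row per pair.
#' @param delays integer vector of delay durations in days; all must be > 0.
#' @param shuffle_seed optional integer; permutes presentation order
#'   reproducibly.
#' @return A `task_design` with `task_id = "delay_discounting"` and trial
#'   columns `immediate_amount`, `delayed_amount`, `delay_days`.
#' @examples
#' d <- delay_design()
#' nrow(d$trials)  # 24
#' @export
delay_design <- function(pairs = default_delay_pairs(),
                         delays = c(7L, 30L, 60L, 90L),
                         shuffle_seed = NULL) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) != 2L) stop("`pairs` must have two columns (immediate, delayed)")
  names(pairs) <- c("immediate_amount", "delayed_amount")
  if (any(!is.finite(pairs$immediate_amount)) || any(!is.finite(pairs$delayed_amount)))
    stop("amounts must be finite")
  bad <- pairs$delayed_amount <= pairs$immediate_amount
  if (any(bad)) {
    stop(sprintf(
      "invalid amount pair(s): delayed amount must exceed immediate amount [%s]",
      paste(sprintf("(%g, %g)", pairs$immediate_amount[bad], pairs$delayed_amount[bad]),
            collapse = ", ")))
  }
  delays <- as.integer(delays)
  if (any(delays <= 0L)) stop("delays must be positive integers (days)")
  grid <- expand.grid(delay_days = delays, pair = seq_len(nrow(pairs)),
                      KEEP.OUT.ATTRS = FALSE)
  trials <- data.frame(
    immediate_amount = pairs$immediate_amount[grid$pair],
    delayed_amount   = pairs$delayed_amount[grid$pair],
    delay_days       = grid$delay_days
  )
  trials <- trials[order(trials$immediate_amount, trials$delayed_amount,
                         trials$delay_days), , drop = FALSE]
  rownames(trials) <- NULL
  shuffle_trials(new_task_design("delay_discounting", trials), shuffle_seed)
}

#' Default immediate/delayed amount pairs for the intertemporal design
#'
#' Six dominance-respecting pairs drawn from the stated immediate
#' \{50, 55, 70, 90\} and delayed \{55, 70, 90, 110\} level sets, spanning
#' delayed/immediate ratios from 1.10 to 1.80; crossed with the four delays
#' they give the 24-trial design.
#'
#' @return A two-column data frame of (immediate, delayed) amounts.
#' @export
default_delay_pairs <- function() {
  data.frame(
    immediate_amount = c(50, 50, 55, 55, 70, 90),
    delayed_amount   = c(55, 70, 70, 90, 90, 110)
  )
}

#' Risk-lottery titration design
#'
#' Builds the risk-aversion series: on each trial the subject chooses
#' between a variable safe amount and a 50/50 lottery over a fixed 300
#' monetary units (expected value 150). The safe amount rises in steps of
#' 10; the default series runs 10..190, i.e. 19 trials (the weakly dominated
#' safe amount 0 is dropped; pass `safe_from = 0` for the 20-level variant).
#'
#' @param safe_from,safe_to,step arithmetic series of safe amounts.
#' @param lottery_amount fixed lottery prize (default 300).
#' @param win_probability lottery win probability (default 0.5).
#' @param shuffle_seed optional integer; permutes presentation order.
#' @return A `task_design` with `task_id = "risk"` and trial columns
#'   `safe_amount`, `lottery_amount`, `win_probability`.
#' @examples
#' r <- risk_design()
#' nrow(r$trials)  # 19
#' @export
risk_design <- function(safe_from = 10, safe_to = 190, step = 10,
                        lottery_amount = 300, win_probability = 0.5,
                        shuffle_seed = NULL) {
  stopifnot(step > 0, safe_to >= safe_from,
            lottery_amount > 0, win_probability > 0, win_probability < 1)
  trials <- data.frame(
    safe_amount = seq(safe_from, safe_to, by = step),
    lottery_amount = lottery_amount,
    win_probability = win_probability
  )
  shuffle_trials(new_task_design("risk", trials), shuffle_seed)
}

#' Mixed-gamble (loss-aversion) titration design
#'
#' Builds the loss-aversion series: 29 trials choosing between the status
#' quo (certain 0) and a 50/50 gamble of gaining a variable amount or losing
#' a fixed 50. Gains rise from 55 to 195 in steps of 5, so every gamble has
#' strictly positive expected value and the gain/loss ratio spans 1.1–3.9.
#'
#' @param gain_from,gain_to,step arithmetic series of gain amounts.
#' @param loss_amount fixed loss (default 50).
#' @param win_probability gamble win probability (default 0.5).
#' @param shuffle_seed optional integer; permutes presentation order.
#' @return A `task_design` with `task_id = "loss"` and trial columns
#'   `gain_amount`, `loss_amount`, `win_probability`.
#' @examples
#' l <- loss_design()
#' nrow(l$trials)  # 29
#' @export
loss_design <- function(gain_from = 55, gain_to = 195, step = 5,
                        loss_amount = 50, win_probability = 0.5,
                        shuffle_seed = NULL) {
  stopifnot(step > 0, gain_to >= gain_from, loss_amount > 0,
            win_probability > 0, win_probability < 1)
  gains <- seq(gain_from, gain_to, by = step)
  ev <- win_probability * gains - (1 - win_probability) * loss_amount
  if (any(ev <= 0))
    stop("loss design must keep every gamble's expected value positive")
  trials <- data.frame(
    gain_amount = gains,
    loss_amount = loss_amount,
    win_probability = win_probability
  )
  shuffle_trials(new_task_design("loss", trials), shuffle_seed)
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("Task design '%s': %d trials\n", x$task_id, nrow(x$trials)))
  print(utils::head(x$trials, 5))
  if (nrow(x$trials) > 5) cat(sprintf("... %d more trials\n", nrow(x$trials) - 5L))
  invisible(x)
}

# Variable-amount column of a design, in the titration sense.
design_variable_column <- function(design) {
  switch(design$task_id,
         risk = "safe_amount",
         loss = "gain_amount",
         stop(sprintf("task '%s' has no titration variable", design$task_id)))
}

#' Serialize / load a task design as CSV
#'
#' One row per trial with `task_id`, `trial_index` (0-based) and the
#' task-specific columns; UTF-8, comma-delimited, header row. The
#' round-trip `read_design(write_design(d))` reproduces `d` exactly.
#'
#' @param design a `task_design`.
#' @param path file path.
#' @return `write_design` returns `path` invisibly; `read_design` returns a
#'   `task_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "task_design"))
  out <- cbind(task_id = design$task_id, design$trials)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!"task_id" %in% names(df)) stop("design file lacks a task_id column")
  task_id <- unique(df$task_id)
  if (length(task_id) != 1L) stop("design file mixes task_id values")
  trials <- df[, setdiff(names(df), "task_id"), drop = FALSE]
  trials <- trials[order(trials$trial_index), , drop = FALSE]
  rownames(trials) <- NULL
  structure(list(task_id = task_id, trials = trials), class = "task_design")
}
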