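# Independent oracles used across tests. These deliberately re-derive
# quantities by the most direct route available (scans, leave-one-out
# refits, closed forms) rather than reusing package internals.

# Direct reversal scan for a titration response vector sorted by the
# variable amount: returns the level at the single accept/reject
# transition (only meaningful for monotone vectors).
oracle_reversal_switch <- function(acc, lev, task) {
  n <- length(acc)
  if (task == "loss") {
    if (all(acc == 0)) return(lev[n])          # rejects everything
    if (all(acc == 1)) return(lev[1])          # accepts everything
    lev[which(diff(acc) == 1)[1] + 1L]         # first 0 -> 1 transition
  } else {
    if (all(acc == 1)) return(lev[n])          # gambles on every trial
    if (all(acc == 0)) return(lev[1])
    lev[which(diff(acc) == -1)[1] + 1L]        # first 1 -> 0 transition
  }
}

# Cronbach's alpha via the mean inter-item covariance identity:
# alpha = k * cbar / (vbar + (k - 1) * cbar)
oracle_alpha_covariance <- function(m) {
  V <- stats::cov(m)
  k <- ncol(m)
  vbar <- mean(diag(V))
  cbar <- mean(V[upper.tri(V)])
  k * cbar / (vbar + (k - 1) * cbar)
}

# Cook's distance by brute-force leave-one-out refitting.
oracle_cooks_loo <- function(formula, data) {
  fit <- stats::lm(formula, data)
  p <- length(coef(fit))
  s2 <- sum(resid(fit)^2) / fit$df.residual
  yh <- stats::predict(fit, data)
  vapply(seq_len(nrow(data)), function(i) {
    fi <- stats::lm(formula, data[-i, , drop = FALSE])
    sum((yh - stats::predict(fi, data))^2) / (p * s2)
  }, numeric(1))
}

# Bernoulli log-likelihood of binary choices under a discounting model,
# computed straight from choice_probability (used as a lattice oracle).
oracle_choice_loglik <- function(records, model, pars) {
  pr <- do.call(choice_probability,
                c(list(trials = records, model = model,
                       temperature = pars[["temperature"]]),
                  as.list(pars[setdiff(names(pars), "temperature")])))
  pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
  y <- records$chose_delayed
  sum(y * log(pr) + (1 - y) * log1p(-pr))
}

# Long item-response table -> participants x items matrix (direct keying
# applied), for reliability checks.
items_wide <- function(responses, items, item_range, reverse_keyed = character()) {
  ids <- unique(responses$participant_id)
  sub <- responses[responses$item_id %in% items, ]
  m <- matrix(NA_real_, length(ids), length(items), dimnames = list(NULL, items))
  m[cbind(match(sub$participant_id, ids), match(sub$item_id, items))] <- sub$response
  rev <- intersect(reverse_keyed, items)
  if (length(rev)) m[, rev] <- item_range[1] + item_range[2] - m[, rev]
  m
}
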