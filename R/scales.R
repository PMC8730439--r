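#' Define a psychometric scale
#'
#' A scale is a set of disjoint subscales (named ordered item-identifier
#' vectors), an inclusive integer response range, an optional set of
#' reverse-keyed items (reflected within the range before aggregation), an
#' aggregation rule per subscale (`"sum"` or `"mean"`), and an optional
#' difference score defined as `subscale[1] - subscale[2]`.
#'
#' @param scale_id identifier, e.g. `"tci"`.
#' @param subscales named list of character vectors of item identifiers.
#' @param item_range inclusive integer bounds `c(min, max)`.
#' @param reverse_keyed character vector of reverse-keyed item identifiers.
#' @param aggregate `"sum"` or `"mean"` scoring per subscale.
#' @param difference optional length-2 character vector of subscale names;
#'   adds a `<scale_id>_diff` score (first minus second).
#' @return a `scale_definition` object.
#' @export
scale_definition <- function(scale_id, subscales, item_range,
                             reverse_keyed = character(),
                             aggregate = c("sum", "mean"),
                             difference = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.list(subscales), length(subscales) >= 1, !is.null(names(subscales)),
            length(item_range) == 2, item_range[1] < item_range[2])
  items <- unlist(subscales, use.names = FALSE)
  if (anyDuplicated(items))
    stop("subscale item sets must be disjoint within a scale")
  if (!all(reverse_keyed %in% items))
    stop("reverse_keyed names items not in the scale")
  if (!is.null(difference)) {
    stopifnot(length(difference) == 2, all(difference %in% names(subscales)))
  }
  structure(list(scale_id = scale_id, subscales = subscales,
                 item_range = as.integer(item_range),
                 reverse_keyed = reverse_keyed, aggregate = aggregate,
                 difference = difference),
            class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("Scale '%s': %d subscale(s), items scored %d-%d, %s-scored\n",
              x$scale_id, length(x$subscales), x$item_range[1], x$item_range[2],
              x$aggregate))
  for (s in names(x$subscales))
    cat(sprintf("  %s: %d items\n", s, length(x$subscales[[s]])))
  invisible(x)
}

#' Default instrument definitions for the compliance battery
#'
#' Concrete shapes for the three instruments:
#' \itemize{
#'   \item `lcb` — locus of control of behaviour, 17 items (8 internal +
#'     9 external), responses 0–5, sum-scored, with the synthetic
#'     internal-minus-external difference score.
#'   \item `mfq` — moral foundations, five 6-item foundations (harm,
#'     fairness, ingroup, authority, purity), responses 0–5, mean-scored.
#'   \item `tci` — reduced temperament and character inventory, seven
#'     8-item subscales, responses 0–5, sum-scored.
#' }
#' A few items per instrument are reverse-keyed to exercise reflection; the
#' keys (like the item counts) are configurable via [scale_definition()].
#'
#' @return named list of `scale_definition` objects.
#' @export
default_scale_definitions <- function() {
  mk_items <- function(prefix, n) sprintf("%s_%02d", prefix, seq_len(n))
  lcb <- scale_definition(
    "lcb",
    subscales = list(internal = mk_items("lcb_int", 8),
                     external = mk_items("lcb_ext", 9)),
    item_range = c(0, 5),
    reverse_keyed = c("lcb_int_03", "lcb_ext_05"),
    aggregate = "sum",
    difference = c("internal", "external"))
  mfq_names <- c("harm", "fairness", "ingroup", "authority", "purity")
  mfq <- scale_definition(
    "mfq",
    subscales = stats::setNames(lapply(mfq_names, function(s) mk_items(paste0("mfq_", s), 6)),
                                mfq_names),
    item_range = c(0, 5),
    aggregate = "mean")
  tci_names <- c("harm_avoidance", "novelty_seeking", "reward_dependence",
                 "persistence", "self_directedness", "cooperativeness",
                 "self_transcendence")
  tci <- scale_definition(
    "tci",
    subscales = stats::setNames(lapply(tci_names, function(s) mk_items(paste0("tci_", s), 8)),
                                tci_names),
    item_range = c(0, 5),
    reverse_keyed = c("tci_harm_avoidance_02", "tci_novelty_seeking_04"),
    aggregate = "sum")
  list(lcb = lcb, mfq = mfq, tci = tci)
}

reverse_key <- function(responses, items, item_range) {
  idx <- names(responses) %in% items
  responses[idx] <- item_range[1] + item_range[2] - responses[idx]
  responses
}

#' Score one scale for a set of participants
#'
#' Reverse-keys, validates the response range, aggregates each subscale by
#' the scale's rule, and (if defined) computes the difference score.
#' Participants with missing items for the scale trigger an error naming
#' the items — listwise exclusion of incomplete participants is done
#' upstream, before scoring.
#'
#' @param responses long item-response table with columns `participant_id`,
#'   `item_id`, `response` (rows for other scales' items are ignored).
#' @param definition a [scale_definition()].
#' @return data frame, one row per participant: `participant_id`, one
#'   column per subscale (named `<scale_id>_<subscale>`), and
#'   `<scale_id>_diff` when a difference score is defined.
#' @examples
#' def <- scale_definition("toy", list(a = c("i1", "i2")), c(0, 5))
#' resp <- data.frame(participant_id = 1, item_id = c("i1", "i2"),
#'                    response = c(4, 5))
#' score_scale(resp, def)
#' @export
score_scale <- function(responses, definition) {
  stopifnot(inherits(definition, "scale_definition"))
  need <- c("participant_id", "item_id", "response")
  miss <- setdiff(need, names(responses))
  if (length(miss)) stop("responses lack column(s): ", paste(miss, collapse = ", "))
  items <- unlist(definition$subscales, use.names = FALSE)
  responses <- responses[responses$item_id %in% items, , drop = FALSE]
  ids <- unique(responses$participant_id)
  rng <- definition$item_range
  m <- matrix(NA_real_, length(ids), length(items),
              dimnames = list(NULL, items))
  m[cbind(match(responses$participant_id, ids),
          match(responses$item_id, items))] <- responses$response
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop(sprintf("participant %s: missing item(s) for scale '%s': %s",
                 ids[bad], definition$scale_id,
                 paste(items[is.na(m[bad, ])], collapse = ", ")))
  }
  rev_items <- intersect(definition$reverse_keyed, items)
  if (length(rev_items))
    m[, rev_items] <- rng[1] + rng[2] - m[, rev_items]
  if (any(m < rng[1] | m > rng[2])) {
    bad <- which(rowSums(m < rng[1] | m > rng[2]) > 0)[1]
    stop(sprintf("participant %s: response(s) outside [%d, %d] for scale '%s'",
                 ids[bad], rng[1], rng[2], definition$scale_id))
  }
  agg <- if (definition$aggregate == "sum") rowSums else rowMeans
  sc <- vapply(definition$subscales,
               function(it) agg(m[, it, drop = FALSE]), numeric(length(ids)))
  if (length(ids) == 1L) sc <- matrix(sc, nrow = 1, dimnames = list(NULL, names(definition$subscales)))
  out <- as.data.frame(sc)
  names(out) <- paste(definition$scale_id, names(definition$subscales), sep = "_")
  if (!is.null(definition$difference))
    out[[paste0(definition$scale_id, "_diff")]] <-
      sc[, definition$difference[1]] - sc[, definition$difference[2]]
  out <- cbind(participant_id = ids, out)
  rownames(out) <- NULL
  out
}

#' Score several scales and merge into a wide trait table
#'
#' @param responses long item-response table (all scales together).
#' @param definitions named list of [scale_definition()]s, e.g.
#'   [default_scale_definitions()].
#' @return wide data frame, one row per participant, all subscale scores.
#' @export
score_scales <- function(responses, definitions = default_scale_definitions()) {
  tabs <- lapply(definitions, function(d) score_scale(responses, d))
  out <- Reduce(function(a, b) merge(a, b, by = "participant_id", sort = FALSE), tabs)
  out[order(out$participant_id), , drop = FALSE]
}

#' Cronbach's alpha internal-consistency reliability
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`
#' with sample variances (denominator `n - 1`). Reverse-keyed items must be
#' reflected before calling.
#'
#' @param item_matrix numeric matrix or data frame, participants in rows,
#'   items in columns; at least 2 items and 3 participants, no missing
#'   values, nonzero total-score variance.
#' @return alpha (scalar).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3)
#' x <- x + rnorm(100)          # shared factor
#' cronbach_alpha(x)
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2) stop("need at least 2 items")
  if (nrow(m) < 3) stop("need at least 3 participants")
  if (anyNA(m)) stop("item matrix contains missing values")
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) stop("total-score variance is zero")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Read/write scale definitions as JSON
#'
#' @param definitions named list of `scale_definition`s.
#' @param path JSON file path.
#' @export
write_scale_definitions <- function(definitions, path) {
  payload <- lapply(definitions, function(d) {
    out <- list(scale_id = d$scale_id, subscales = d$subscales,
                item_range = d$item_range, reverse_keyed = d$reverse_keyed,
                aggregate = d$aggregate)
    if (!is.null(d$difference)) out$difference <- d$difference
    out
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scale_definitions
#' @export
read_scale_definitions <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  lapply(raw, function(d) {
    scale_definition(d$scale_id,
                     subscales = as.list(d$subscales),
                     item_range = d$item_range,
                     reverse_keyed = if (length(d$reverse_keyed))
                       unlist(d$reverse_keyed) else character(),
                     aggregate = d$aggregate,
                     difference = if (length(d$difference)) d$difference else NULL)
  })
}
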