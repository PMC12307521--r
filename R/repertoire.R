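#' Apply the repertoire inclusion threshold
#'
#' A gesture action enters the species repertoire when it has been observed
#' at least `min_tokens` times (default three); rarer actions are removed
#' together with all their tokens and listed in the exclusion report.
#'
#' @param tokens validated token table.
#' @param min_tokens minimum token count for inclusion.
#' @return list with `tokens` (kept rows), `actions` (kept action labels),
#'   and `excluded` (data.frame of removed actions with counts).
#' @export
apply_repertoire_threshold <- function(tokens, min_tokens = 3) {
  counts <- table(tokens$gesture_action)
  keep <- names(counts)[counts >= min_tokens]
  excl <- names(counts)[counts < min_tokens]
  list(
    tokens = tokens[tokens$gesture_action %in% keep, , drop = FALSE],
    actions = sort(keep),
    excluded = data.frame(gesture_action = excl,
                          token_count = as.integer(counts[excl]),
                          row.names = NULL, stringsAsFactors = FALSE)
  )
}

#' Token-contribution table of the gesture-action repertoire
#'
#' Per action: token count, percentage contribution, cumulative percentage
#' (actions ordered from most to least frequent), and the deviation from
#' the average contribution, i.e. the count each action would have under
#' uniform use of the repertoire (total tokens / number of actions).
#' Percentages are printed half-away-from-zero at one decimal; deviations
#' are rounded to integers. Ties in token count are broken alphabetically.
#'
#' @param tokens thresholded token table.
#' @return data.frame of class `"morphrep_contribution"` with attribute
#'   `average_contribution` (rounded) and `average_contribution_raw`.
#' @export
build_contribution_table <- function(tokens) {
  if (nrow(tokens) == 0)
    stop_morphrep("empty repertoire", "morphrep_empty_error")
  counts <- table(tokens$gesture_action)
  ord <- order(-as.integer(counts), names(counts))
  cnt <- as.integer(counts)[ord]
  total <- sum(cnt)
  avg <- total / length(cnt)
  share <- cnt / total
  out <- data.frame(
    gesture_action = names(counts)[ord],
    token_count = cnt,
    contribution_pct = round_half_up(100 * share, 1),
    deviation_from_average = round_half_up(cnt - avg, 0),
    cumulative_pct = round_half_up(100 * cumsum(share), 1),
    share = share,
    stringsAsFactors = FALSE
  )
  attr(out, "average_contribution") <- round_half_up(avg, 0)
  attr(out, "average_contribution_raw") <- avg
  class(out) <- c("morphrep_contribution", "data.frame")
  out
}

#' Repertoire of regular use
#'
#' The minimal prefix of the frequency-ordered contribution table whose
#' summed (unrounded) token share reaches `target_fraction`. The default
#' 0.695 operationalizes "about 70 percent of tokens" while tolerating
#' one-decimal presentation rounding of the cumulative column.
#'
#' @param contribution a [build_contribution_table()] result.
#' @param target_fraction fraction of tokens to cover, in (0, 1].
#' @return character vector of action labels, most frequent first.
#' @export
regular_use_set <- function(contribution, target_fraction = 0.695) {
  if (!is.numeric(target_fraction) || target_fraction <= 0 ||
      target_fraction > 1)
    stop_morphrep("target_fraction must be in (0, 1]",
                  "morphrep_parameter_error")
  cum <- cumsum(contribution$share)
  k <- which(cum >= target_fraction - 1e-12)[1]
  contribution$gesture_action[seq_len(k)]
}

#' Detection-asymptote (accumulation) curve
#'
#' Plots the number of distinct repertoire units observed so far against
#' the number of tokens, in observed (coding) order. The asymptote is
#' operationalized as the index of the final first occurrence
#' (`last_novelty_index`); its fraction of the dataset is also reported.
#' With `n_permutations > 0` a rarefaction envelope over random token
#' orders is added (mean and 2.5/97.5 percent quantiles per index).
#'
#' @param tokens token table carrying `order_index`.
#' @param unit_of `"action"` (gesture actions) or `"morph"` (requires a
#'   `morph_id` column; unassigned tokens, `NA`, are dropped).
#' @param n_permutations number of random re-orderings for the envelope.
#' @param seed seed for the permutations.
#' @return list of class `"morphrep_accumulation"`: `points` (data.frame
#'   `token_index`, `units`), `last_novelty_index`,
#'   `last_novelty_fraction`, `n_units`, and optionally `envelope`.
#' @export
accumulation_curve <- function(tokens, unit_of = c("action", "morph"),
                               n_permutations = 0, seed = 1L) {
  unit_of <- tryCatch(match.arg(unit_of), error = function(e)
    stop_morphrep("unit_of must be 'action' or 'morph'",
                  "morphrep_parameter_error"))
  units <- if (unit_of == "action") tokens$gesture_action else tokens$morph_id
  if (is.null(units))
    stop_morphrep("tokens lack a morph_id column", "morphrep_parameter_error")
  keep <- !is.na(units)
  units <- units[keep][order(tokens$order_index[keep])]
  n <- length(units)
  cum <- cumsum(!duplicated(units))
  last_idx <- if (n) max(which(!duplicated(units))) else 0L
  out <- list(points = data.frame(token_index = seq_len(n), units = cum),
              last_novelty_index = last_idx,
              last_novelty_fraction = if (n) last_idx / n else NA_real_,
              n_units = if (n) cum[n] else 0L)
  if (n_permutations > 0) {
    set.seed(seed)
    curves <- matrix(0L, nrow = n_permutations, ncol = n)
    for (b in seq_len(n_permutations)) {
      perm <- units[sample.int(n)]
      curves[b, ] <- cumsum(!duplicated(perm))
    }
    out$envelope <- data.frame(
      token_index = seq_len(n),
      mean = colMeans(curves),
      lower = apply(curves, 2, stats::quantile, 0.025),
      upper = apply(curves, 2, stats::quantile, 0.975)
    )
  }
  class(out) <- "morphrep_accumulation"
  out
}

#' Overall gesturing rate
#'
#' Total tokens per hour of group-follow observation, summed over the
#' unique (group, season) effort records.
#'
#' @param tokens token table.
#' @param effort effort table ([read_effort()] layout).
#' @return tokens per follow-hour (numeric scalar).
#' @export
overall_rate <- function(tokens, effort) {
  gs <- unique(effort[, c("group_id", "season_id", "follow_hours")])
  hours <- sum(gs$follow_hours)
  if (hours <= 0)
    stop_morphrep("total follow hours must be positive",
                  "morphrep_parameter_error")
  nrow(tokens) / hours
}
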