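#' Proportional subsample for inter-rater reliability
#'
#' Draws a random subset whose per-action sample sizes are proportional to
#' each gesture action's representation in the dataset (largest-remainder
#' rounding of the per-action quotas), totalling `round(fraction * n)`
#' tokens. Sampling within an action is without replacement and
#' deterministic given the seed.
#'
#' @param tokens token table.
#' @param fraction fraction of the dataset to re-code, in (0, 1].
#' @param seed integer seed.
#' @return token subset (same columns as `tokens`).
#' @export
proportional_subsample <- function(tokens, fraction = 0.05, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop_morphrep("fraction must be in (0, 1]", "morphrep_parameter_error")
  if (fraction == 1) return(tokens)
  set.seed(seed)
  cnt <- table(tokens$gesture_action)
  target <- round(fraction * nrow(tokens))
  alloc <- largest_remainder(as.numeric(cnt), target)
  rows <- integer(0)
  for (i in seq_along(cnt)) {
    if (alloc[i] == 0) next
    pool <- which(tokens$gesture_action == names(cnt)[i])
    rows <- c(rows, sample_vec(pool, alloc[i]))
  }
  tokens[sort(rows), , drop = FALSE]
}

#' Cohen's kappa and percentage agreement
#'
#' Unweighted kappa for two equal-length categorical label sequences:
#' `p_o` is the fraction of exact matches, `p_e = sum_c m1_c * m2_c` the
#' chance agreement from the two raters' marginals, and
#' `kappa = (p_o - p_e) / (1 - p_e)`. With `p_e = 1` (both raters use a
#' single shared category) kappa is undefined and reported as `NA`.
#'
#' @param labels1,labels2 label vectors of equal length.
#' @param variable optional variable name carried into the result.
#' @return data.frame of class `"morphrep_agreement"`: `variable`,
#'   `n_items`, `percentage_agreement`, `kappa`.
#' @export
agreement_stats <- function(labels1, labels2, variable = NA_character_) {
  if (length(labels1) != length(labels2))
    stop_morphrep("label sequences differ in length",
                  "morphrep_parameter_error")
  n <- length(labels1)
  labels1 <- as.character(labels1)
  labels2 <- as.character(labels2)
  lev <- union(labels1, labels2)
  p_o <- mean(labels1 == labels2)
  m1 <- table(factor(labels1, lev)) / n
  m2 <- table(factor(labels2, lev)) / n
  p_e <- sum(as.numeric(m1) * as.numeric(m2))
  kappa <- if (abs(1 - p_e) < 1e-12) NA_real_ else (p_o - p_e) / (1 - p_e)
  out <- data.frame(variable = variable, n_items = n,
                    percentage_agreement = 100 * p_o, kappa = kappa,
                    stringsAsFactors = FALSE)
  class(out) <- c("morphrep_agreement", "data.frame")
  out
}

#' Per-variable agreement between two raters
#'
#' @param rater1 token table (or any table with `token_id` and the coded
#'   variables).
#' @param rater2 second-rater table with `token_id` and the same variable
#'   columns (e.g. from [generate_rater_pair()]).
#' @param variables variable names to compare (default: all shared coded
#'   columns of `rater2`).
#' @return data.frame with one [agreement_stats()] row per variable.
#' @export
rater_agreement <- function(rater1, rater2, variables = NULL) {
  if (is.null(variables))
    variables <- setdiff(intersect(names(rater1), names(rater2)),
                         "token_id")
  idx <- match(rater2$token_id, rater1$token_id)
  if (anyNA(idx))
    stop_morphrep("rater2 token_id not found in rater1",
                  "morphrep_parameter_error")
  do.call(rbind, lapply(variables, function(v)
    agreement_stats(rater1[[v]][idx], rater2[[v]], variable = v)))
}
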