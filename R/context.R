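#' Behavioural-context distribution at the communication level
#'
#' Context is a property of the communication (the signaller's behaviour at
#' its end), carried redundantly on every token of the communication; a
#' conflict within a communication is a coding defect and raises a
#' validation error. Counts are per communication, not per token. Contexts
#' contributing less than `pool_below` percent of the raw distribution are
#' pooled into `"Other"`; `"Unknown"` (context could not be estimated) is
#' kept separate and never pooled. Pooling is idempotent: `"Other"` and
#' `"Unknown"` rows pass through unchanged.
#'
#' @param tokens token table with `communication_id` and `context_after`.
#' @param pool_below pooling threshold in percent (default 1).
#' @return data.frame of class `"morphrep_context"`: `context`, `n`,
#'   `pct` (half-up, one decimal), ordered by decreasing count with
#'   `Other`/`Unknown` last; attribute `n_communications`.
#' @export
context_distribution <- function(tokens, pool_below = 1) {
  split_ctx <- split(tokens$context_after, tokens$communication_id)
  bad <- names(split_ctx)[vapply(split_ctx,
                                 function(x) length(unique(x)) > 1,
                                 logical(1))]
  if (length(bad))
    stop_morphrep(paste0("conflicting context within communication(s): ",
                         paste(bad, collapse = ", ")),
                  "morphrep_validation_error")
  ctx <- vapply(split_ctx, `[`, "", 1)
  n_comm <- length(ctx)
  cnt <- table(ctx)
  raw_pct <- 100 * as.numeric(cnt) / n_comm
  lab <- names(cnt)
  is_unknown <- tolower(lab) == "unknown"
  is_other <- tolower(lab) == "other"
  pool <- raw_pct < pool_below & !is_unknown & !is_other
  named <- data.frame(context = lab[!pool & !is_unknown & !is_other],
                      n = as.integer(cnt[!pool & !is_unknown & !is_other]),
                      stringsAsFactors = FALSE)
  named <- named[order(-named$n, named$context), , drop = FALSE]
  extra <- list()
  n_other <- sum(cnt[pool]) + sum(cnt[is_other])
  if (n_other > 0)
    extra$other <- data.frame(context = "Other",
                              n = as.integer(n_other))
  if (any(is_unknown))
    extra$unknown <- data.frame(context = "Unknown",
                                n = as.integer(sum(cnt[is_unknown])))
  out <- rbind(named, extra$other, extra$unknown)
  out$pct <- round_half_up(100 * out$n / n_comm, 1)
  rownames(out) <- NULL
  attr(out, "n_communications") <- n_comm
  class(out) <- c("morphrep_context", "data.frame")
  out
}
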