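#' Round half away from zero
#'
#' Presentation rounding used for percentage and deviation columns; base
#' `round()` rounds half to even, which does not match the usual printed
#' tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Largest-remainder integer allocation
#'
#' Allocates an integer `total` across categories proportionally to
#' `weights`: each category receives `floor(total * w_i / sum(w))`, and the
#' remaining units go to the categories with the largest fractional
#' remainders (ties broken by position, for determinism).
#'
#' @param weights non-negative numeric weights.
#' @param total non-negative integer to allocate.
#' @return integer vector summing to `total`, same length as `weights`.
#' @export
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0, sum(weights) > 0 || total == 0)
  if (total == 0) return(integer(length(weights)))
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# log(sum(exp(x))) along rows of a matrix, guarding -Inf rows
logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_morphrep <- function(msg, class) {
  stop(structure(class = c(class, "morphrep_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
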