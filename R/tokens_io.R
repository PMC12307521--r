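#' Read and validate a gesture-token table
#'
#' Reads a UTF-8 comma-separated token table (one row per gesture token, the
#' export format of ELAN-style gesture coding) and validates it against a
#' modifier vocabulary. Rows carrying modifier or action levels outside the
#' declared vocabulary are rejected with an error naming the offending rows;
#' nothing is silently coerced.
#'
#' Required columns: `token_id`, `communication_id`, `signaller_id`,
#' `recipient_id`, `gesture_action`, `body_part`, `contact_recipient`,
#' `lateral_use`, `repetition`, `context_after`, `group_id`, `season_id`,
#' `order_index`, `outcome`. Chronology is carried by the integer
#' `order_index` (strictly orderable), not timestamps.
#'
#' @param path path to a CSV file with a header row.
#' @param vocab a [morphrep_vocab()]; modifier levels are checked against the
#'   declared sets plus the reserved `"unclear"` / `"not_applicable"`.
#' @return a `data.frame` of validated tokens, one row per token.
#' @export
read_tokens <- function(path, vocab = morphrep_vocab()) {
  if (!file.exists(path)) stop_morphrep(paste0("no such file: ", path),
                                        "morphrep_io_error")
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8", check.names = FALSE)
  validate_tokens(df, vocab)
}

#' @rdname read_tokens
#' @param tokens a data.frame of tokens (already in memory).
#' @export
validate_tokens <- function(tokens, vocab = morphrep_vocab()) {
  req <- token_columns()
  missing <- setdiff(req, names(tokens))
  if (length(missing))
    stop_morphrep(paste0("missing required column(s): ",
                         paste(missing, collapse = ", ")),
                  "morphrep_schema_error")
  df <- as.data.frame(tokens, stringsAsFactors = FALSE)[, req]
  for (col in setdiff(req, "order_index")) df[[col]] <- as.character(df[[col]])
  oi <- suppressWarnings(as.integer(df$order_index))
  if (anyNA(oi))
    stop_morphrep("order_index must be integer", "morphrep_schema_error")
  df$order_index <- oi

  bad <- character()
  if (anyDuplicated(df$token_id))
    bad <- c(bad, paste0("duplicate token_id: ",
                         paste(unique(df$token_id[duplicated(df$token_id)]),
                               collapse = ", ")))
  self <- which(df$signaller_id == df$recipient_id)
  if (length(self))
    bad <- c(bad, paste0("signaller equals recipient in row(s): ",
                         paste(self, collapse = ", ")))
  reserved <- c("unclear", "not_applicable")
  for (m in modifier_names()) {
    ok <- df[[m]] %in% c(vocab$modifiers[[m]], reserved)
    if (!all(ok))
      bad <- c(bad, paste0("unknown ", m, " level in row(s): ",
                           paste(which(!ok), collapse = ", "), " (",
                           paste(unique(df[[m]][!ok]), collapse = ", "), ")"))
  }
  if (!is.null(vocab$actions)) {
    ok <- df$gesture_action %in% vocab$actions
    if (!all(ok))
      bad <- c(bad, paste0("unknown gesture_action in row(s): ",
                           paste(which(!ok), collapse = ", ")))
  }
  ok <- df$context_after %in% c(vocab$contexts, "unknown", "other")
  if (!all(ok))
    bad <- c(bad, paste0("unknown context_after in row(s): ",
                         paste(which(!ok), collapse = ", ")))
  ok <- df$outcome %in% c("successful", "unsuccessful", "unknown")
  if (!all(ok))
    bad <- c(bad, paste0("unknown outcome in row(s): ",
                         paste(which(!ok), collapse = ", ")))
  if (length(bad))
    stop_morphrep(paste(bad, collapse = "\n"), "morphrep_validation_error")
  rownames(df) <- NULL
  df
}

token_columns <- function() {
  c("token_id", "communication_id", "signaller_id", "recipient_id",
    "gesture_action", "body_part", "contact_recipient", "lateral_use",
    "repetition", "context_after", "group_id", "season_id", "order_index",
    "outcome")
}

#' Write a token table
#'
#' Writes tokens in the same CSV dialect [read_tokens()] consumes (UTF-8,
#' comma-separated, fixed column order), so that `read(write(T))` equals `T`.
#'
#' @param tokens validated token data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tokens <- function(tokens, path) {
  utils::write.csv(tokens[, token_columns()], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read the individuals table
#'
#' Columns: `individual_id`, `sex` (`female`/`male`), `birth_date`
#' (ISO-8601), `parity_events` (semicolon-separated ISO dates of offspring
#' births, empty for none), `groups` (semicolon-separated
#' `group_id:season_id` membership pairs).
#'
#' @param path CSV path.
#' @return data.frame of individuals.
#' @export
read_individuals <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  req <- c("individual_id", "sex", "birth_date", "parity_events", "groups")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop_morphrep(paste0("missing required column(s): ",
                         paste(missing, collapse = ", ")),
                  "morphrep_schema_error")
  if (!all(df$sex %in% c("female", "male")))
    stop_morphrep("sex must be 'female' or 'male'",
                  "morphrep_validation_error")
  males <- df$sex == "male" & nzchar(df$parity_events)
  if (any(males))
    stop_morphrep("parity_events recorded for male individual(s)",
                  "morphrep_validation_error")
  df
}

#' Read the observation-effort table
#'
#' One row per (individual, season): `season_id`, `group_id`,
#' `individual_id`, `follow_hours` (that group's follow hours in that
#' season, repeated across its members), `video_hours` (hours of footage
#' featuring the individual). Group-level follow effort is recovered as the
#' unique (group, season) values.
#'
#' @param path CSV path.
#' @return data.frame of effort records.
#' @export
read_effort <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8",
                        colClasses = c(season_id = "character",
                                       group_id = "character",
                                       individual_id = "character"))
  req <- c("season_id", "group_id", "individual_id", "follow_hours",
           "video_hours")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop_morphrep(paste0("missing required column(s): ",
                         paste(missing, collapse = ", ")),
                  "morphrep_schema_error")
  if (any(df$follow_hours < 0, na.rm = TRUE) ||
      any(df$video_hours < 0, na.rm = TRUE))
    stop_morphrep("effort hours must be non-negative",
                  "morphrep_validation_error")
  df
}

#' Cross-referential validation of the three input tables
#'
#' Total check that never mutates its inputs: every signaller and recipient
#' must exist in the individuals table, every token's (group, season) must
#' exist in the effort table, and `order_index` must have no duplicates.
#' Failures are enumerated in the returned report, not raised.
#'
#' @param tokens validated token table.
#' @param individuals individuals table.
#' @param effort effort table.
#' @return data.frame report with columns `kind`, `id`, `detail`; zero rows
#'   when the dataset is fully consistent.
#' @export
validate_dataset <- function(tokens, individuals, effort) {
  fail <- list()
  add <- function(kind, id, detail)
    fail[[length(fail) + 1L]] <<- data.frame(kind = kind, id = id,
                                             detail = detail)
  known <- individuals$individual_id
  for (i in which(!(tokens$signaller_id %in% known)))
    add("orphan signaller", tokens$token_id[i], tokens$signaller_id[i])
  for (i in which(!(tokens$recipient_id %in% known)))
    add("orphan recipient", tokens$token_id[i], tokens$recipient_id[i])
  gs_tok <- unique(paste(tokens$group_id, tokens$season_id, sep = "\r"))
  gs_eff <- unique(paste(effort$group_id, effort$season_id, sep = "\r"))
  for (gs in setdiff(gs_tok, gs_eff)) {
    parts <- strsplit(gs, "\r", fixed = TRUE)[[1]]
    add("unknown group-season", parts[1], parts[2])
  }
  dup <- unique(tokens$order_index[duplicated(tokens$order_index)])
  for (d in dup)
    add("order collision", as.character(d),
        paste(tokens$token_id[tokens$order_index == d], collapse = ";"))
  if (length(fail)) do.call(rbind, fail)
  else data.frame(kind = character(), id = character(), detail = character())
}
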