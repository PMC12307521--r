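# Small in-code fixtures shared across the suite.

# Minimal token table: one row per element of `actions`, with sensible
# defaults for every other column. Extra columns can be overridden
# vector-wise through `...`.
toy_tokens <- function(actions, ...) {
  n <- length(actions)
  df <- data.frame(
    token_id = sprintf("t%04d", seq_len(n)),
    communication_id = sprintf("c%04d", seq_len(n)),
    signaller_id = rep("ind1", n),
    recipient_id = rep("ind2", n),
    gesture_action = actions,
    body_part = rep("hand", n),
    contact_recipient = rep("contact", n),
    lateral_use = rep("left", n),
    repetition = rep("single", n),
    context_after = rep("resting", n),
    group_id = rep("g1", n),
    season_id = rep("s1", n),
    order_index = seq_len(n),
    outcome = rep("successful", n),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

toy_individuals <- function(ids = c("ind1", "ind2")) {
  data.frame(
    individual_id = ids,
    sex = rep(c("male", "female"), length.out = length(ids)),
    birth_date = "2010-01-01",
    parity_events = "",
    groups = "g1:s1",
    stringsAsFactors = FALSE
  )
}

toy_effort <- function(ids = c("ind1", "ind2"), follow = 10, video = 5) {
  data.frame(season_id = "s1", group_id = "g1", individual_id = ids,
             follow_hours = follow, video_hours = video,
             stringsAsFactors = FALSE)
}

# Modifier-vector matrix built from a list of (config, count) pairs;
# configs are named character vectors.
planted_vectors <- function(...) {
  blocks <- list(...)
  do.call(rbind, lapply(blocks, function(b)
    matrix(rep(b$config, b$count), ncol = length(b$config), byrow = TRUE,
           dimnames = list(NULL, names(b$config)))))
}

# Tiny two-action synthetic config for determinism / plumbing tests.
toy_synth_config <- function(epsilon = 0, seed = 1L) {
  acts <- data.frame(gesture_action = c("push", "reach"),
                     count = c(30L, 20L), is_new = c(FALSE, TRUE),
                     epsilon = epsilon, stringsAsFactors = FALSE)
  comps <- list(
    push = list(weights = c(0.5, 0.5),
                configs = matrix(c("hand", "contact", "left", "single",
                                   "foot", "no_contact", "right",
                                   "repeated"),
                                 nrow = 2, byrow = TRUE,
                                 dimnames = list(NULL, modifier_names()))),
    reach = list(weights = 1,
                 configs = matrix(c("hand", "no_contact", "both", "single"),
                                  nrow = 1,
                                  dimnames = list(NULL, modifier_names())))
  )
  pop <- data.frame(
    individual_id = c("a1", "a2", "a3"),
    sex = c("male", "female", "female"),
    birth_date = c("2005-01-01", "2010-06-01", "2019-01-01"),
    parity_events = c("", "2021-01-01", ""),
    groups = "g1:s1", group_id = "g1", weight = c(2, 1, 1),
    stringsAsFactors = FALSE
  )
  eff <- data.frame(season_id = "s1", group_id = "g1",
                    individual_id = c("a1", "a2", "a3"),
                    follow_hours = 25, video_hours = 10,
                    stringsAsFactors = FALSE)
  synthetic_config(actions = acts, components = comps,
                   unclear = list(rate = 0), population = pop,
                   effort = eff, seed = seed)
}

token_columns_for_test <- function() {
  c("token_id", "communication_id", "signaller_id", "recipient_id",
    "gesture_action", "body_part", "contact_recipient", "lateral_use",
    "repetition", "context_after", "group_id", "season_id", "order_index",
    "outcome")
}

# all permutations of a small vector (with duplicates)
combinat_permutations <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(combinat_permutations(x[-i]), function(p)
      c(x[i], p)))
  out
}

# Shared calibrated run for the acceptance suite (computed once per
# session; ~2 s).
calibrated_run <- local({
  cache <- NULL
  function(seed = 1L) {
    if (is.null(cache)) cache <<- run_synthetic_pipeline(seed = seed)
    cache
  }
})
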