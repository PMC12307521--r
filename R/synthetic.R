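#' Specify a synthetic gesture dataset with planted latent structure
#'
#' A synthetic config is a complete statement of the world the analysis
#' assumes: a table of planted gesture actions (each a mixture of modifier
#' configurations, its "morphs"), per-modifier noise, an unclear-coding
#' model, a behavioural-context distribution over communications, a
#' population of individuals with ages/sex/parity, and an
#' observation-effort table. [generate_dataset()] realizes it into token,
#' individuals, effort and ground-truth tables, deterministically for a
#' given seed.
#'
#' @param actions data.frame with columns `gesture_action`, `count`
#'   (planted token count) or `share` (probability; converted to counts by
#'   largest remainder), `is_new` (logical: potentially species-specific),
#'   `epsilon` (per-modifier flip probability).
#' @param components named list: for each action, `list(weights, configs)`
#'   where `configs` is a k x m character matrix (columns = applicable
#'   modifiers, values = levels) and `weights` a length-k probability
#'   vector. Mixture weights must sum to 1.
#' @param vocab a [morphrep_vocab()] declaring levels and applicability.
#' @param n_tokens total token count (required when `actions$share` is used).
#' @param unclear either `list(rate = p)` (each token has probability `p` of
#'   getting one unclear modifier, count realized as `round(p * n)`) or
#'   `list(per_action = c(action = count, ...))` for exact stratified
#'   placement.
#' @param contexts named probability vector over behavioural contexts; any
#'   remaining mass is assigned to `"unknown"`.
#' @param population data.frame of individuals: `individual_id`, `sex`,
#'   `birth_date`, `parity_events`, `groups`, plus generator columns
#'   `group_id` (primary group) and `weight` (expected token share).
#' @param effort data.frame in the [read_effort()] layout.
#' @param comm_size_probs probability vector over communication lengths
#'   `1..length(comm_size_probs)` (tokens per communication).
#' @param outcome_probs named probabilities for `successful`,
#'   `unsuccessful`, `unknown`.
#' @param last_novel optional `list(action=, index=)`: plants the final
#'   first-occurrence of the accumulation curve (computed over actions with
#'   >= 3 tokens) at exactly `index`.
#' @param seed default seed used by [generate_dataset()].
#' @return an object of class `"morphrep_synth_config"`.
#' @export
synthetic_config <- function(actions, components, vocab = morphrep_vocab(),
                             n_tokens = NULL,
                             unclear = list(rate = 0.03),
                             contexts = NULL,
                             population, effort,
                             comm_size_probs = c(0.35, 0.30, 0.18, 0.11, 0.06),
                             outcome_probs = c(successful = 0.55,
                                               unsuccessful = 0.35,
                                               unknown = 0.10),
                             last_novel = NULL,
                             seed = 1L) {
  stopifnot(is.data.frame(actions), "gesture_action" %in% names(actions))
  if (is.null(actions$count)) {
    if (is.null(actions$share) || is.null(n_tokens))
      stop_morphrep("actions need either a count column or share + n_tokens",
                    "morphrep_config_error")
    stopifnot(all(actions$share >= 0))
  }
  if (is.null(actions$epsilon)) actions$epsilon <- 0
  if (is.null(actions$is_new)) actions$is_new <- FALSE
  for (a in actions$gesture_action) {
    comp <- components[[a]]
    if (is.null(comp))
      stop_morphrep(paste0("no components for action ", a),
                    "morphrep_config_error")
    if (abs(sum(comp$weights) - 1) > 1e-8)
      stop_morphrep(paste0("component weights of ", a, " do not sum to 1"),
                    "morphrep_config_error")
    cfg <- comp$configs
    if (nrow(cfg) != length(comp$weights))
      stop_morphrep(paste0("weights/configs mismatch for ", a),
                    "morphrep_config_error")
    app <- applicable_modifiers(vocab, a)
    if (!all(colnames(cfg) %in% app))
      stop_morphrep(paste0("component of ", a,
                           " uses a non-applicable modifier"),
                    "morphrep_config_error")
    for (m in colnames(cfg)) {
      if (!all(cfg[, m] %in% vocab$modifiers[[m]]))
        stop_morphrep(paste0("component of ", a, " uses unknown level of ",
                             m), "morphrep_config_error")
    }
  }
  if (is.null(contexts))
    contexts <- c(resting = 0.169, playing = 0.141, grooming = 0.136,
                  traveling = 0.104, affiliating = 0.099, sexual = 0.070,
                  carrying = 0.061, feeding = 0.046, nursing = 0.044,
                  agonistic = 0.012)
  if (sum(contexts) > 1 + 1e-8)
    stop_morphrep("context probabilities exceed 1", "morphrep_config_error")
  structure(
    list(actions = actions, components = components, vocab = vocab,
         n_tokens = n_tokens, unclear = unclear, contexts = contexts,
         population = population, effort = effort,
         comm_size_probs = comm_size_probs, outcome_probs = outcome_probs,
         last_novel = last_novel, seed = seed),
    class = "morphrep_synth_config"
  )
}

#' Generate a synthetic gesture dataset
#'
#' Realizes a [synthetic_config()]: per-action token counts are allocated by
#' largest remainder from the planted counts/shares (so empirical shares
#' match their targets as closely as integer counts allow at any n), tokens
#' are drawn from the planted component mixture, per-modifier noise flips
#' each applicable modifier with probability epsilon to a uniformly random
#' other level, unclear levels are injected after noise, and tokens are
#' ordered, grouped into communications, and attributed to signallers.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed (defaults to `config$seed`); identical
#'   (config, seed) pairs give identical output.
#' @return list with elements `tokens`, `individuals`, `effort`, `truth`
#'   (token_id, gesture_action, component index as planted) and `config`.
#' @export
generate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "morphrep_synth_config"))
  set.seed(seed)
  vocab <- config$vocab
  acts <- config$actions
  counts <- if (!is.null(acts$count)) as.integer(acts$count)
            else largest_remainder(acts$share, config$n_tokens)
  n <- sum(counts)
  mods <- modifier_names()

  action <- rep(acts$gesture_action, counts)
  comp_idx <- integer(n)
  modmat <- matrix("not_applicable", nrow = n, ncol = length(mods),
                   dimnames = list(NULL, mods))
  for (i in seq_len(nrow(acts))) {
    a <- acts$gesture_action[i]
    rows <- which(action == a)
    comp <- config$components[[a]]
    sizes <- largest_remainder(comp$weights, length(rows))
    ci <- rep(seq_along(comp$weights), sizes)
    comp_idx[rows] <- ci
    cfg <- comp$configs
    for (m in colnames(cfg)) modmat[rows, m] <- cfg[ci, m]
    # independent per-modifier flip to a uniformly random other level
    eps <- acts$epsilon[i]
    if (eps > 0) {
      for (m in colnames(cfg)) {
        flip <- rows[stats::runif(length(rows)) < eps]
        if (length(flip)) {
          lv <- vocab$modifiers[[m]]
          cur <- modmat[flip, m]
          alt <- vapply(cur, function(x) sample(setdiff(lv, x), 1), "")
          modmat[flip, m] <- alt
        }
      }
    }
  }

  # unclear injection (after noise): one randomly chosen applicable
  # modifier per selected token is set to "unclear"
  unclear_rows <- integer()
  if (!is.null(config$unclear$per_action)) {
    ua <- config$unclear$per_action
    for (a in names(ua)) {
      rows <- which(action == a)
      if (ua[[a]] > length(rows))
        stop_morphrep(paste0("unclear count exceeds tokens of ", a),
                      "morphrep_config_error")
      unclear_rows <- c(unclear_rows, sample_vec(rows, ua[[a]]))
    }
  } else if (!is.null(config$unclear$rate) && config$unclear$rate > 0) {
    unclear_rows <- sample_vec(seq_len(n), round(config$unclear$rate * n))
  }
  for (r in unclear_rows) {
    app <- applicable_modifiers(vocab, action[r])
    modmat[r, sample_vec(app, 1)] <- "unclear"
  }

  ord <- plant_order(action, counts, acts$gesture_action, config$last_novel)

  # communications over the ordered token stream
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, sample.int(length(config$comm_size_probs), 1,
                                 prob = config$comm_size_probs))
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
  sizes <- sizes[sizes > 0]
  n_comm <- length(sizes)
  comm_of <- rep(seq_len(n_comm), sizes)

  pop <- config$population
  eff <- config$effort
  gs <- unique(eff[, c("group_id", "season_id", "follow_hours")])
  ctx_lv <- c(names(config$contexts), "unknown")
  ctx_p <- c(config$contexts, max(0, 1 - sum(config$contexts)))
  sig_i <- sample.int(nrow(pop), n_comm, replace = TRUE, prob = pop$weight)
  comm <- data.frame(
    signaller_id = pop$individual_id[sig_i],
    group_id = pop$group_id[sig_i],
    recipient_id = NA_character_,
    season_id = NA_character_,
    context = sample(ctx_lv, n_comm, replace = TRUE, prob = ctx_p),
    outcome = sample(names(config$outcome_probs), n_comm, replace = TRUE,
                     prob = config$outcome_probs),
    stringsAsFactors = FALSE
  )
  for (g in unique(comm$group_id)) {
    rows <- which(comm$group_id == g)
    members <- pop$individual_id[pop$group_id == g]
    seas <- gs[gs$group_id == g, ]
    comm$season_id[rows] <- sample_vec(seas$season_id, length(rows),
                                       replace = TRUE,
                                       prob = seas$follow_hours)
    for (r in rows) {
      others <- setdiff(members, comm$signaller_id[r])
      if (!length(others)) others <- setdiff(pop$individual_id,
                                             comm$signaller_id[r])
      comm$recipient_id[r] <- sample_vec(others, 1)
    }
  }

  pos_of <- ord                       # position of each original row
  cid <- comm_of[pos_of]
  tokens <- data.frame(
    token_id = sprintf("t%05d", seq_len(n)),
    communication_id = sprintf("c%05d", cid),
    signaller_id = comm$signaller_id[cid],
    recipient_id = comm$recipient_id[cid],
    gesture_action = action,
    body_part = modmat[, "body_part"],
    contact_recipient = modmat[, "contact_recipient"],
    lateral_use = modmat[, "lateral_use"],
    repetition = modmat[, "repetition"],
    context_after = comm$context[cid],
    group_id = comm$group_id[cid],
    season_id = comm$season_id[cid],
    order_index = pos_of,
    outcome = comm$outcome[cid],
    stringsAsFactors = FALSE
  )
  truth <- data.frame(token_id = tokens$token_id,
                      gesture_action = action, component = comp_idx,
                      unclear = seq_len(n) %in% unclear_rows,
                      stringsAsFactors = FALSE)
  individuals <- pop[, c("individual_id", "sex", "birth_date",
                         "parity_events", "groups")]
  rownames(individuals) <- NULL
  list(tokens = tokens, individuals = individuals, effort = eff,
       truth = truth, config = config)
}

# sample() without its scalar-x surprise
sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# Returns a position for every token row such that, within the subsequence
# of actions holding >= 3 tokens, the last first-occurrence is planted at
# `last_novel$index` (when given); otherwise a plain random permutation.
plant_order <- function(action, counts, action_names, last_novel) {
  n <- length(action)
  if (is.null(last_novel)) return(sample.int(n))
  kept_actions <- action_names[counts >= 3]
  la <- last_novel$action
  idx <- last_novel$index
  if (!la %in% kept_actions)
    stop_morphrep("last_novel action is below the repertoire threshold",
                  "morphrep_config_error")
  kept <- which(action %in% kept_actions)
  lrows <- which(action == la)
  other <- setdiff(kept, lrows)
  if (idx - 1 < length(kept_actions) - 1 || idx > length(kept))
    stop_morphrep("last_novel index infeasible", "morphrep_config_error")
  # one seed token per other action guarantees first occurrences before idx
  seeds <- vapply(setdiff(kept_actions, la),
                  function(a) sample_vec(which(action == a), 1), 1L)
  fill <- sample_vec(setdiff(other, seeds), idx - 1 - length(seeds))
  prefix <- sample_vec(c(seeds, fill), idx - 1)
  first_l <- sample_vec(lrows, 1)
  suffix <- sample_vec(setdiff(kept, c(prefix, first_l)),
                       length(kept) - idx)
  kept_seq <- c(prefix, first_l, suffix)
  rest <- setdiff(seq_len(n), kept)
  pos <- integer(n)
  rest_pos <- sort(sample_vec(seq_len(n), length(rest)))
  pos[rest] <- rest_pos
  pos[kept_seq] <- setdiff(seq_len(n), rest_pos)
  pos
}

#' Simulate a second rater from per-variable confusion matrices
#'
#' For each listed variable, a second-rater label is drawn per token from
#' the confusion-matrix row of the first rater's label, emulating an
#' independent re-coding whose expected agreement (and hence Cohen's kappa)
#' is computable analytically from the confusion matrix and the label
#' marginals.
#'
#' @param tokens token table (first rater's coding).
#' @param confusion named list of row-stochastic square matrices with
#'   identical row/column level names; names select token columns.
#' @param seed integer seed.
#' @return data.frame with `token_id` and one re-coded column per variable.
#' @export
generate_rater_pair <- function(tokens, confusion, seed = 1L) {
  set.seed(seed)
  out <- data.frame(token_id = tokens$token_id, stringsAsFactors = FALSE)
  for (v in names(confusion)) {
    cm <- confusion[[v]]
    if (is.null(rownames(cm)) || is.null(colnames(cm)) ||
        !identical(rownames(cm), colnames(cm)) ||
        any(cm < 0) || any(abs(rowSums(cm) - 1) > 1e-8))
      stop_morphrep(paste0("confusion matrix for ", v,
                           " is not row-stochastic"),
                    "morphrep_config_error")
    lab <- tokens[[v]]
    if (!all(lab %in% rownames(cm)))
      stop_morphrep(paste0("labels of ", v, " missing from confusion rows"),
                    "morphrep_config_error")
    out[[v]] <- vapply(lab, function(l)
      sample(colnames(cm), 1, prob = cm[l, ]), "", USE.NAMES = FALSE)
  }
  out
}
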