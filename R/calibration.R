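#' Calibrated synthetic profile: a Bwindi-style mountain-gorilla dataset
#'
#' [bwindi_config()] returns a [synthetic_config()] whose planted structure
#' mirrors the published structure of a wild mountain-gorilla gesture
#' dataset: 3220 tokens over 75 gesture actions, of which 12 rare actions
#' (17 tokens, all carrying an unclear modifier) fall below the three-token
#' repertoire threshold, leaving 63 repertoire actions; 18 of those have
#' fewer than ten tokens (99 tokens, "unspecified"); the remaining 45 carry
#' planted morph mixtures: 19 unimorphic and 26 polymorphic actions with 89
#' planted morphs (2-8 per action). 97 tokens in total carry an unclear
#' modifier level, so the latent-class stage analyzes 3024 instances.
#' Fifteen actions are flagged potentially species-specific and contribute
#' 352 tokens. The final first occurrence among repertoire actions is
#' planted at token 1530 of 3203. Group-follow effort totals 553 h across
#' four social units and four seasons; 27 of the 49 individuals belong to
#' the two focal units.
#'
#' Token counts per action are fixed integers (largest-remainder images of
#' the published contribution percentages), so repertoire-level statistics
#' are identical across seeds; randomness enters through modifier noise
#' (epsilon = 0.02 per applicable modifier), unclear placement, token order,
#' signaller attribution and contexts.
#'
#' @param epsilon per-modifier flip probability for every action.
#' @return a [synthetic_config()].
#' @export
bwindi_config <- function(epsilon = 0.02) {
  vocab <- bwindi_vocab()
  acts <- bwindi_actions()
  comps <- bwindi_components(acts, vocab)
  unimorphic <- acts$gesture_action[acts$n_components == 1 & acts$count >= 10]
  sub3 <- acts$gesture_action[acts$count < 3]
  per_action <- c(
    stats::setNames(acts$count[match(sub3, acts$gesture_action)], sub3),
    stats::setNames(
      largest_remainder(acts$count[match(unimorphic, acts$gesture_action)],
                        80L),
      unimorphic)
  )
  acts$epsilon <- epsilon
  acts$epsilon[acts$gesture_action %in% sub3] <- 0  # their tokens are unclear anyway
  synthetic_config(
    actions = acts[, c("gesture_action", "count", "is_new", "epsilon")],
    components = comps,
    vocab = vocab,
    unclear = list(per_action = per_action[per_action > 0]),
    population = bwindi_population(),
    effort = bwindi_effort(),
    last_novel = list(action = "jump", index = 1530L),
    seed = 1L
  )
}

#' @rdname bwindi_config
#' @export
bwindi_vocab <- function() {
  morphrep_vocab(
    applicability = list(
      chest_beat = c("body_part", "lateral_use", "repetition"),
      stomp_object = c("body_part", "lateral_use", "repetition"),
      locomote_stiff_run = c("body_part", "lateral_use", "repetition"),
      jump = c("body_part", "contact_recipient", "repetition"),
      roll_over = c("body_part", "contact_recipient", "repetition"),
      lay_on = c("body_part", "contact_recipient", "lateral_use")
    )
  )
}

#' @rdname bwindi_config
#' @export
bwindi_actions <- function() {
  # 30 common actions: published contribution percentages of the 3203-token
  # repertoire; counts by largest remainder over their 2809-token mass.
  common <- data.frame(
    gesture_action = c(
      "push", "present", "grab", "touch", "object_move", "hit_object",
      "chest_beat_informal", "pull", "gaze_stance", "reach", "stiff_stance",
      "hit_recipient", "locomote_stiff_walk", "embrace", "grab_hold",
      "touch_long", "raise", "bite_threat", "hit_recipient_soft",
      "hit_self", "kiss", "locomote_stiff_run", "chest_beat", "bite",
      "fling", "lean_in", "object_shake", "stroke", "stomp_object",
      "place_on_object"),
    pct = c(8.6, 6.5, 6.2, 6.0, 5.0, 4.8, 4.5, 3.9, 3.9, 3.8, 3.6, 3.5,
            2.6, 2.6, 2.3, 2.2, 1.9, 1.4, 1.4, 1.4, 1.3, 1.3, 1.2, 1.2,
            1.2, 1.2, 1.2, 1.1, 1.0, 1.0),
    n_components = c(8, 6, 6, 5, 5, 4, 4, 4, 4, 4, 3, 3, 3, 3, 3, 3, 3,
                     1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    is_new = FALSE, stringsAsFactors = FALSE
  )
  common$is_new[common$gesture_action %in%
                  c("gaze_stance", "lean_in", "place_on_object")] <- TRUE
  common$count <- largest_remainder(common$pct, 2809L)
  common$pct <- NULL

  # 15 uncommon but analyzable actions (<1% each, >= 10 tokens); the
  # potentially species-specific ones are weighted so specific tokens
  # total 352 across the dataset
  uncommon <- data.frame(
    gesture_action = c("body_cross", "locomote_recipient", "bump_into",
                       "jab", "object_stance", "hit_tap", "lay_on",
                       "hit_fake", "head_avert", "spin_pirouette", "beckon",
                       "lunge", "locomote_gallop", "over_stance", "swing"),
    count = c(25L, 15L, 15L, 15L, 15L, 14L, 14L, 14L, 14L,
              26L, 26L, 26L, 26L, 25L, 25L),
    n_components = c(rep(2L, 9), rep(1L, 6)),
    is_new = c(rep(TRUE, 9), rep(FALSE, 6)),
    stringsAsFactors = FALSE
  )

  # 18 unspecified actions (3 <= tokens < 10): in the repertoire, excluded
  # from morph detection
  unspecified <- data.frame(
    gesture_action = c("hit_non_recipient", "turn", "settle_beside",
                       "dangle", "shake", "pivot", "head_stand",
                       "rake_object", "locomote_bipedal", "rub",
                       "spin_roulade", "hit_object_object", "object_drop",
                       "object_mouth", "roll_over", "stance_bipedal",
                       "throw_object", "jump"),
    count = c(6L, 5L, 5L, 6L, 6L, 6L, 6L, 6L, 6L, 6L, 6L,
              5L, 5L, 5L, 5L, 5L, 5L, 5L),
    n_components = 1L,
    is_new = c(TRUE, TRUE, TRUE, rep(FALSE, 15)),
    stringsAsFactors = FALSE
  )

  # 12 actions seen fewer than three times (17 tokens): below the
  # repertoire threshold
  sub3 <- data.frame(
    gesture_action = c("arm_swing", "clap", "slap_ground", "foot_stomp",
                       "poke", "head_nod", "wrist_shake", "back_roll",
                       "chin_rest", "leg_kick", "side_roll", "tumble"),
    count = c(2L, 2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    n_components = 1L, is_new = FALSE, stringsAsFactors = FALSE
  )
  rbind(common, uncommon, unspecified, sub3)
}

# Mixture weights by number of planted components: skewed (the first morph
# dominates) but with no component so small that its detectability under
# the BIC criterion would hinge on noise realizations.
component_weights <- function(k) {
  switch(k,
         1,
         c(0.6, 0.4),
         c(0.45, 0.3, 0.25),
         c(0.35, 0.25, 0.22, 0.18),
         c(0.26, 0.22, 0.19, 0.17, 0.16),
         c(0.21, 0.19, 0.17, 0.15, 0.14, 0.14),
         c(0.17, 0.16, 0.15, 0.14, 0.13, 0.13, 0.12),
         c(0.15, 0.14, 0.13, 0.13, 0.12, 0.11, 0.11, 0.11))
}

# Eight modifier configurations, any two differing in at least two
# modifiers; the first k rows (pairwise Hamming distance >= 2, >= 3 for the
# first four) are the planted components of a k-morph action.
component_table <- function() {
  lv <- default_modifier_levels()
  idx <- matrix(c(1, 1, 1, 1,
                  4, 2, 2, 2,
                  5, 1, 3, 2,
                  6, 2, 3, 1,
                  2, 2, 1, 1,
                  3, 1, 2, 1,
                  1, 2, 3, 2,
                  2, 1, 2, 2), ncol = 4, byrow = TRUE)
  out <- matrix("", nrow = 8, ncol = 4,
                dimnames = list(NULL, modifier_names()))
  for (j in 1:4) out[, j] <- lv[[j]][idx[, j]]
  out
}

bwindi_components <- function(actions, vocab) {
  tab <- component_table()
  comps <- list()
  for (i in seq_len(nrow(actions))) {
    a <- actions$gesture_action[i]
    k <- actions$n_components[i]
    app <- applicable_modifiers(vocab, a)
    comps[[a]] <- list(weights = component_weights(k),
                       configs = tab[seq_len(k), app, drop = FALSE])
  }
  comps
}

#' @rdname bwindi_config
#' @export
bwindi_seasons <- function() {
  data.frame(
    season_id = c("s1", "s2", "s3", "s4"),
    start = as.Date(c("2022-06-01", "2022-12-01", "2023-06-01",
                      "2023-12-01")),
    end = as.Date(c("2022-08-31", "2023-02-28", "2023-08-31",
                    "2024-02-29")),
    midpoint = as.Date(c("2022-07-01", "2023-01-01", "2023-07-01",
                         "2024-01-01")),
    stringsAsFactors = FALSE
  )
}

#' @rdname bwindi_config
#' @export
bwindi_population <- function() {
  mk <- function(id, sex, birth, group, weight, parity = "") {
    data.frame(individual_id = id, sex = sex, birth_date = birth,
               parity_events = parity,
               groups = paste(paste0(group, ":", c("s1", "s2", "s3", "s4")),
                              collapse = ";"),
               group_id = group, weight = weight, stringsAsFactors = FALSE)
  }
  rows <- list(
    # mukiza focal unit (14)
    mk("MK",     "male",   "1997-07-01", "mukiza", 73),
    mk("fa1",    "female", "2004-03-01", "mukiza", 92, "2019-05-01"),
    mk("fa2",    "female", "2006-06-01", "mukiza", 92, "2018-06-01"),
    mk("fa3",    "female", "2000-09-01", "mukiza", 92, "2021-07-01"),
    mk("fa4",    "female", "2008-02-01", "mukiza", 92, "2021-09-01"),
    mk("ka_f",   "female", "2001-05-01", "mukiza", 92),
    mk("bw_f",   "female", "2011-07-01", "mukiza", 170),
    mk("bb_m",   "male",   "2011-05-01", "mukiza", 170),
    mk("sub_m",  "male",   "2015-07-01", "mukiza", 170),
    mk("juv_m1", "male",   "2018-01-01", "mukiza", 160),
    mk("juv_f1", "female", "2018-07-01", "mukiza", 160),
    mk("inf_m1", "male",   "2021-07-01", "mukiza", 35),
    mk("inf_m2", "male",   "2019-12-01", "mukiza", 35),
    mk("inf_f1", "female", "2021-09-01", "mukiza", 35),
    # bitukura focal unit (13)
    mk("sb_m2",  "male",   "2000-07-01", "bitukura", 92),
    mk("am_m3",  "male",   "2008-07-01", "bitukura", 92),
    mk("fb1",    "female", "2003-04-01", "bitukura", 92, "2020-02-01"),
    mk("fb2",    "female", "2005-10-01", "bitukura", 92, "2019-11-01"),
    mk("fb3",    "female", "2007-01-01", "bitukura", 92, "2022-01-01"),
    mk("bw3_f",  "female", "2012-01-01", "bitukura", 170, "2023-08-01"),
    mk("bw2_f",  "female", "2013-07-01", "bitukura", 170),
    mk("nf2_f",  "female", "2011-09-01", "bitukura", 170),
    mk("bb2_m",  "male",   "2013-01-01", "bitukura", 170),
    mk("juv_m2", "male",   "2018-05-01", "bitukura", 160),
    mk("inf_f2", "female", "2021-05-01", "bitukura", 35),
    mk("inf_m3", "male",   "2019-10-01", "bitukura", 35),
    mk("inf_m4", "male",   "2021-12-10", "bitukura", 35)
  )
  other <- list()
  specs <- list(c("rushegura", 11), c("oruzogo", 11))
  births <- c("1999-01-01", "2003-05-01", "2005-08-01", "2008-04-01",
              "2010-06-01", "2012-09-01", "2014-11-01", "2016-02-01",
              "2018-08-01", "2020-03-01", "2021-10-01")
  sexes <- c("male", "female", "female", "female", "male", "female",
             "male", "female", "male", "female", "male")
  for (sp in specs) {
    g <- sp[1]
    for (j in seq_len(as.integer(sp[2]))) {
      par <- if (sexes[j] == "female" && births[j] < "2008-01-01")
        "2020-06-01" else ""
      other[[length(other) + 1]] <-
        mk(paste0(substr(g, 1, 2), sprintf("%02d", j)), sexes[j],
           births[j], g, 343 / 22, par)
    }
  }
  do.call(rbind, c(rows, other))
}

#' @rdname bwindi_config
#' @export
bwindi_effort <- function() {
  follow <- list(mukiza = c(36, 36, 36, 35), bitukura = c(40, 40, 40, 40),
                 rushegura = c(32, 32, 31, 30), oruzogo = c(32, 31, 31, 31))
  pop <- bwindi_population()
  out <- list()
  for (i in seq_len(nrow(pop))) {
    g <- pop$group_id[i]
    out[[i]] <- data.frame(
      season_id = c("s1", "s2", "s3", "s4"), group_id = g,
      individual_id = pop$individual_id[i],
      follow_hours = follow[[g]],
      video_hours = round(0.04 * pop$weight[i] + 3, 1),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
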