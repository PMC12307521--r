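#' Run the full repertoire-analysis pipeline
#'
#' Orchestrates the stages in order: validation, repertoire threshold,
#' contribution table and regular-use set, accumulation curves, morph
#' detection (latent-class analysis per action), individual statistics by
#' maturation/sex class, context distribution, and (when a second-rater
#' table is supplied) inter-rater agreement. Any stage error aborts with a
#' stage-tagged message. All thresholds and seeds are recorded in the
#' report, and identical inputs + settings + seed give identical reports.
#'
#' @param tokens validated token table (see [read_tokens()]).
#' @param individuals individuals table.
#' @param effort effort table.
#' @param vocab a [morphrep_vocab()].
#' @param seasons seasons table for maturation classes.
#' @param min_tokens repertoire inclusion threshold (tokens per action).
#' @param action_min minimum tokens for LCA inclusion.
#' @param morph_min minimum tokens per morph.
#' @param k_max maximum latent classes per action.
#' @param n_restarts EM restarts.
#' @param regular_use_target token fraction for the regular-use repertoire.
#' @param new_actions optional labels of potentially species-specific
#'   gesture actions (an input flag, not derived).
#' @param focal_groups optional group ids restricting individual-level
#'   statistics to comparable social units (default: all groups).
#' @param rater2 optional second-rater table for [rater_agreement()].
#' @param n_permutations rarefaction permutations for accumulation curves.
#' @param seed integer master seed.
#' @return a list of class `"morphrep_report"`.
#' @export
run_pipeline <- function(tokens, individuals, effort,
                         vocab = morphrep_vocab(),
                         seasons = bwindi_seasons(),
                         min_tokens = 3, action_min = 10, morph_min = 5,
                         k_max = 8, n_restarts = 20,
                         regular_use_target = 0.695,
                         new_actions = NULL, focal_groups = NULL,
                         rater2 = NULL, n_permutations = 0, seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
  }

  stage("validation", {
    if (nrow(tokens) == 0) stop("no tokens")
    tokens <- validate_tokens(tokens, vocab)
    report <- validate_dataset(tokens, individuals, effort)
    if (nrow(report) > 0)
      stop("dataset inconsistent: ",
           paste(unique(report$kind), collapse = ", "))
  })

  thr <- stage("repertoire_threshold",
               apply_repertoire_threshold(tokens, min_tokens))
  contribution <- stage("contribution",
                        build_contribution_table(thr$tokens))
  regular <- stage("regular_use",
                   regular_use_set(contribution, regular_use_target))
  acc_action <- stage("accumulation",
                      accumulation_curve(thr$tokens, "action",
                                         n_permutations = n_permutations,
                                         seed = seed + 7L))

  prepared <- stage("lca_prepare",
                    prepare_lca_inputs(thr$tokens, vocab, action_min))
  detection <- stage("lca_fit",
                     detect_morphs(prepared, k_max = k_max,
                                   morph_min = morph_min,
                                   n_restarts = n_restarts,
                                   seed = seed + 13L))
  morphsum <- stage("morph_summary", summarize_morph_repertoire(detection))

  acc_morph <- stage("morph_accumulation", {
    mt <- thr$tokens
    assign_all <- unlist(lapply(detection$actions, `[[`, "assignment"))
    mt$morph_id <- unname(assign_all[mt$token_id])
    accumulation_curve(mt, "morph", seed = seed + 11L)
  })

  ind <- stage("individual_stats", {
    tk <- tokens
    ef <- effort
    if (!is.null(focal_groups)) {
      tk <- tk[tk$group_id %in% focal_groups, , drop = FALSE]
      ef <- ef[ef$group_id %in% focal_groups, , drop = FALSE]
    }
    assignments <- assign_maturation_classes(
      individuals[individuals$individual_id %in% tk$signaller_id, ],
      seasons)
    list(summaries = individual_summaries(tk, ef),
         assignments = assignments,
         by_class = summarize_by_class(tk, ef, assignments))
  })

  contexts <- stage("context_stats", context_distribution(tokens))

  reliability <- if (!is.null(rater2))
    stage("reliability", rater_agreement(tokens, rater2)) else NULL

  # unclear tokens across the original dataset (pre-threshold), for the
  # filter-cascade account
  any_unclear <- rep(FALSE, nrow(tokens))
  for (m in modifier_names()) {
    applicable_here <- vapply(unique(tokens$gesture_action), function(a)
      m %in% applicable_modifiers(vocab, a), logical(1))
    acts_with_m <- names(applicable_here)[applicable_here]
    any_unclear <- any_unclear |
      (tokens[[m]] == "unclear" & tokens$gesture_action %in% acts_with_m)
  }
  n_unclear_total <- sum(any_unclear)

  new_kept <- intersect(new_actions %||% character(), thr$actions)
  new_tokens <- sum(thr$tokens$gesture_action %in% new_kept)

  structure(list(
    stages = data.frame(
      n_total = nrow(tokens),
      n_repertoire_tokens = nrow(thr$tokens),
      n_repertoire_actions = length(thr$actions),
      n_unclear_total = n_unclear_total,
      n_lca_analyzed = prepared$report$n_analyzed,
      n_lca_actions = morphsum$n_analyzed_actions
    ),
    settings = list(min_tokens = min_tokens, action_min = action_min,
                    morph_min = morph_min, k_max = k_max,
                    n_restarts = n_restarts,
                    regular_use_target = regular_use_target, seed = seed),
    excluded_actions = thr$excluded,
    contribution = contribution,
    regular_use = regular,
    shared = if (length(new_kept)) list(
      n_new = length(new_kept),
      n_shared = length(thr$actions) - length(new_kept),
      shared_fraction = 1 - length(new_kept) / length(thr$actions),
      new_token_count = new_tokens,
      new_token_share = new_tokens / nrow(thr$tokens)) else NULL,
    accumulation = list(action = acc_action, morph = acc_morph),
    lca_report = prepared$report,
    morph_summary = morphsum,
    detection = detection,
    individual = ind,
    contexts = contexts,
    reliability = reliability,
    overall_rate = overall_rate(tokens, effort)
  ), class = "morphrep_report")
}

#' Run the pipeline on a synthetic configuration
#'
#' Generates a dataset from `config` and analyzes it with the thresholds of
#' the calibrated profile; the planted `is_new` flags feed the
#' shared-repertoire statistics and the two focal units feed the
#' individual statistics.
#'
#' @param config a [synthetic_config()] (default [bwindi_config()]).
#' @param seed master seed for generation and analysis.
#' @param ... further arguments to [run_pipeline()].
#' @return list: `report` (the [run_pipeline()] result) and `data` (the
#'   generated dataset).
#' @export
run_synthetic_pipeline <- function(config = bwindi_config(), seed = 1L,
                                   ...) {
  data <- generate_dataset(config, seed = seed)
  report <- run_pipeline(
    data$tokens, data$individuals, data$effort, vocab = config$vocab,
    new_actions =
      config$actions$gesture_action[as.logical(config$actions$is_new)],
    focal_groups = c("mukiza", "bitukura"),
    seed = seed, ...)
  list(report = report, data = data)
}

#' @export
print.morphrep_report <- function(x, ...) {
  s <- x$stages
  cat("Gestural repertoire analysis\n")
  cat(sprintf("  tokens: %d total, %d in repertoire (%d actions)\n",
              s$n_total, s$n_repertoire_tokens, s$n_repertoire_actions))
  cat(sprintf("  average contribution under uniform use: %d tokens/action\n",
              as.integer(attr(x$contribution, "average_contribution"))))
  cat(sprintf("  regular-use repertoire: %d actions\n",
              length(x$regular_use)))
  cat(sprintf("  LCA: %d instances across %d actions\n",
              s$n_lca_analyzed, s$n_lca_actions))
  m <- x$morph_summary
  cat(sprintf("  morphs: %d units (%d unimorphic, %d polymorphic with %d morphs, %d unspecified)\n",
              m$n_units, m$n_unimorphic, m$n_polymorphic,
              m$n_polymorphic_morphs, m$n_unspecified))
  if (!is.null(x$shared))
    cat(sprintf("  shared with other species: %d/%d actions (%.0f%%)\n",
                x$shared$n_shared, s$n_repertoire_actions,
                100 * x$shared$shared_fraction))
  cat(sprintf("  overall rate: %.2f tokens/h (%.0f rounded)\n",
              x$overall_rate, round_half_up(x$overall_rate, 0)))
  cat(sprintf("  action asymptote: token %d (%.0f%% of dataset)\n",
              x$accumulation$action$last_novelty_index,
              100 * x$accumulation$action$last_novelty_fraction))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the tables as fixed-column CSV files plus a `summary.json` with
#' the scalar results.
#'
#' @param report a `"morphrep_report"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(report$stages, "stages.csv")
  wr(as.data.frame(report$contribution), "contribution.csv")
  wr(data.frame(gesture_action = report$regular_use), "regular_use.csv")
  wr(report$morph_summary$morph_table, "morphs.csv")
  wr(report$accumulation$action$points, "accumulation_action.csv")
  wr(report$accumulation$morph$points, "accumulation_morph.csv")
  wr(report$individual$summaries, "individuals.csv")
  wr(report$individual$by_class$summary, "class_summary.csv")
  wr(as.data.frame(report$contexts), "contexts.csv")
  if (!is.null(report$reliability)) wr(report$reliability,
                                       "reliability.csv")
  m <- report$morph_summary
  jsonlite::write_json(list(
    settings = report$settings,
    stages = as.list(report$stages),
    average_contribution = attr(report$contribution,
                                "average_contribution"),
    regular_use_size = length(report$regular_use),
    morph_units = m$n_units,
    unimorphic = m$n_unimorphic, polymorphic = m$n_polymorphic,
    polymorphic_morphs = m$n_polymorphic_morphs,
    unspecified = m$n_unspecified,
    mean_morphs_per_polymorphic = m$mean_morphs_per_polymorphic,
    unassigned_fraction = m$unassigned_fraction,
    overall_rate = report$overall_rate,
    asymptote_index = report$accumulation$action$last_novelty_index,
    asymptote_fraction = report$accumulation$action$last_novelty_fraction,
    shared = report$shared
  ), file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  invisible(dir)
}
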