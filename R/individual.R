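#' Maturation class from age, sex and parity
#'
#' Four broad maturation categories: `cat1_infant` (0-3 years, both
#' sexes), `cat2_juvenile` (>3-6), `cat3_subadult_blackback_nulliparous`
#' (>6-8 both sexes; blackback males >8-12; nulliparous females 8-<12),
#' `cat4_adult` (males >12; parous females; nulliparous females >= 12).
#' Parity overrides age for females: a parous female is an adult.
#'
#' @param age_years age in years (non-negative).
#' @param sex `"female"` or `"male"`.
#' @param parous logical; has the female given birth (ignored for males)?
#' @return the class label.
#' @export
maturation_class <- function(age_years, sex, parous = FALSE) {
  if (is.na(age_years) || age_years < 0)
    stop_morphrep("age must be non-negative", "morphrep_parameter_error")
  if (!sex %in% c("female", "male"))
    stop_morphrep("sex must be 'female' or 'male'",
                  "morphrep_parameter_error")
  if (sex == "female" && isTRUE(parous)) return("cat4_adult")
  if (age_years <= 3) return("cat1_infant")
  if (age_years <= 6) return("cat2_juvenile")
  if (age_years <= 8) return("cat3_subadult_blackback_nulliparous")
  if (sex == "male") {
    if (age_years <= 12) return("cat3_subadult_blackback_nulliparous")
    return("cat4_adult")
  }
  if (age_years < 12) return("cat3_subadult_blackback_nulliparous")
  "cat4_adult"
}

#' Assign one maturation class per individual and season
#'
#' An individual occupies exactly one class within a season. When the
#' individual crosses a class boundary inside the season, the class most
#' represented in that season's tokens wins (majority rule; ties go to the
#' later class). A female whose first birth falls within a season counts
#' as parous for that whole season. By default the age at the season
#' midpoint is used.
#'
#' @param individual one row of the individuals table.
#' @param season one row of a seasons table (`season_id`, `start`, `end`,
#'   `midpoint` dates).
#' @param token_class_counts optional named counts of that season's tokens
#'   per candidate class, used to resolve a within-season boundary
#'   crossing.
#' @return data.frame: `individual_id`, `season_id`, `class`, `sex`.
#' @export
assign_maturation_class <- function(individual, season,
                                    token_class_counts = NULL) {
  birth <- as.Date(individual$birth_date)
  age_at <- function(d) as.numeric(as.Date(d) - birth) / 365.25
  parity <- parse_dates(individual$parity_events)
  # parous for the season if any birth on or before the season's end
  parous <- length(parity) > 0 && min(parity) <= as.Date(season$end)
  cls_start <- maturation_class(age_at(season$start), individual$sex, parous)
  cls_end <- maturation_class(age_at(season$end), individual$sex, parous)
  cls <- maturation_class(age_at(season$midpoint), individual$sex, parous)
  if (cls_start != cls_end && !is.null(token_class_counts)) {
    cand <- intersect(names(token_class_counts), c(cls_start, cls_end))
    if (length(cand)) {
      cnt <- token_class_counts[cand]
      cls <- cand[order(-cnt, match(cand, c(cls_end, cls_start)))][1]
    }
  }
  data.frame(individual_id = individual$individual_id,
             season_id = season$season_id, class = cls,
             sex = individual$sex, stringsAsFactors = FALSE)
}

parse_dates <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) return(as.Date(character()))
  as.Date(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Maturation assignments for a whole dataset
#'
#' @param individuals individuals table.
#' @param seasons seasons table (see [bwindi_seasons()] for the layout).
#' @return data.frame of per-(individual, season) assignments.
#' @export
assign_maturation_classes <- function(individuals,
                                      seasons = bwindi_seasons()) {
  out <- list()
  for (i in seq_len(nrow(individuals))) {
    for (s in seq_len(nrow(seasons))) {
      out[[length(out) + 1]] <-
        assign_maturation_class(individuals[i, ], seasons[s, ])
    }
  }
  do.call(rbind, out)
}

#' Individual repertoire size
#'
#' `IRS_1` counts every distinct gesture action a signaller produced (even
#' once); `IRS_3` counts actions used at least three times by that
#' signaller.
#'
#' @param tokens token table.
#' @param threshold minimum tokens per action per signaller (1 or 3).
#' @param signallers optional signaller ids to report (defaults to those
#'   present); unknown ids raise an error.
#' @return named integer vector, one entry per signaller.
#' @export
compute_irs <- function(tokens, threshold = 1, signallers = NULL) {
  present <- unique(tokens$signaller_id)
  if (is.null(signallers)) signallers <- sort(present)
  if (!all(signallers %in% present))
    stop_morphrep("unknown signaller id(s)", "morphrep_parameter_error")
  out <- vapply(signallers, function(s) {
    cnt <- table(tokens$gesture_action[tokens$signaller_id == s])
    sum(cnt >= threshold)
  }, 1L)
  stats::setNames(as.integer(out), signallers)
}

#' Individual gesturing rates
#'
#' `IGR_obs` is tokens per hour of the signaller's group-follow observation
#' time (follow hours summed over the seasons the individual appears in the
#' effort table); `IGR_vid` is tokens per hour of video footage featuring
#' the individual. Zero-denominator rates are reported as `NA` (undefined),
#' never as zero.
#'
#' @param tokens token table.
#' @param effort effort table.
#' @param signallers signaller ids to report (default: those in `tokens`).
#' @return data.frame: `individual_id`, `token_count`, `follow_hours`,
#'   `video_hours`, `igr_obs`, `igr_vid`.
#' @export
compute_igr <- function(tokens, effort, signallers = NULL) {
  if (is.null(signallers)) signallers <- sort(unique(tokens$signaller_id))
  rows <- lapply(signallers, function(s) {
    nt <- sum(tokens$signaller_id == s)
    ef <- effort[effort$individual_id == s, , drop = FALSE]
    fh <- sum(unique(ef[, c("group_id", "season_id",
                            "follow_hours")])$follow_hours)
    vh <- sum(ef$video_hours)
    data.frame(individual_id = s, token_count = nt, follow_hours = fh,
               video_hours = vh,
               igr_obs = if (fh > 0) nt / fh else NA_real_,
               igr_vid = if (vh > 0) nt / vh else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-individual summaries (IRS and IGR)
#'
#' @param tokens token table (typically restricted to the focal groups).
#' @param effort effort table.
#' @return data.frame with `irs_1`, `irs_3`, `igr_obs`, `igr_vid`,
#'   `token_count` per signaller.
#' @export
individual_summaries <- function(tokens, effort) {
  igr <- compute_igr(tokens, effort)
  igr$irs_1 <- compute_irs(tokens, 1, igr$individual_id)
  igr$irs_3 <- compute_irs(tokens, 3, igr$individual_id)
  igr[, c("individual_id", "token_count", "irs_1", "irs_3",
          "follow_hours", "video_hours", "igr_obs", "igr_vid")]
}

#' Summaries by maturation class and sex
#'
#' Individuals contribute one data point per maturation class they occupy
#' across seasons (within a season, exactly one class); IRS and IGR for a
#' data point are computed from that individual's tokens and effort in the
#' seasons of that class.
#'
#' @param tokens token table.
#' @param effort effort table.
#' @param assignments per-(individual, season) classes, from
#'   [assign_maturation_classes()].
#' @return list: `points` (one row per individual x class) and `summary`
#'   (per class x sex: n, mean/sd/range of IRS_1, IRS_3, IGR_obs).
#' @export
summarize_by_class <- function(tokens, effort, assignments) {
  key <- unique(assignments[, c("individual_id", "class", "sex")])
  pts <- list()
  for (i in seq_len(nrow(key))) {
    id <- key$individual_id[i]
    cls <- key$class[i]
    seas <- assignments$season_id[assignments$individual_id == id &
                                    assignments$class == cls]
    tk <- tokens[tokens$signaller_id == id & tokens$season_id %in% seas, ,
                 drop = FALSE]
    if (nrow(tk) == 0) next  # no data point without tokens in that class
    ef <- effort[effort$season_id %in% seas, , drop = FALSE]
    s <- individual_summaries(tk, ef)
    s$class <- cls
    s$sex <- key$sex[i]
    pts[[length(pts) + 1]] <- s
  }
  points <- do.call(rbind, pts)
  agg <- function(v) c(n = sum(!is.na(v)),
                       mean = mean(v, na.rm = TRUE),
                       sd = if (sum(!is.na(v)) > 1)
                         stats::sd(v, na.rm = TRUE) else NA,
                       min = suppressWarnings(min(v, na.rm = TRUE)),
                       max = suppressWarnings(max(v, na.rm = TRUE)))
  groups <- unique(points[, c("class", "sex")])
  srows <- list()
  for (i in seq_len(nrow(groups))) {
    sel <- points$class == groups$class[i] & points$sex == groups$sex[i]
    row <- data.frame(class = groups$class[i], sex = groups$sex[i],
                      n = sum(sel), stringsAsFactors = FALSE)
    for (v in c("irs_1", "irs_3", "igr_obs", "igr_vid")) {
      a <- agg(points[[v]][sel])
      row[[paste0(v, "_mean")]] <- a[["mean"]]
      row[[paste0(v, "_sd")]] <- a[["sd"]]
      row[[paste0(v, "_min")]] <- a[["min"]]
      row[[paste0(v, "_max")]] <- a[["max"]]
    }
    srows[[i]] <- row
  }
  list(points = points, summary = do.call(rbind, srows))
}
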