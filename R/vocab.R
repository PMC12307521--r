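#' Modifier vocabulary and applicability map
#'
#' A vocabulary declares the closed set of levels for each of the four
#' gesture modifiers (body part, contact with recipient, lateral use,
#' repetition), the behavioural-context labels, and (optionally) the set of
#' admissible gesture-action labels. Two level strings are reserved across
#' all modifiers: `"unclear"` (the coder could not determine the level) and
#' `"not_applicable"` (the modifier is not meaningful for that gesture
#' action). The applicability map says which modifiers are meaningful for
#' which actions; modifiers absent from an action's entry are carried as
#' `"not_applicable"` and ignored by the latent-class analysis.
#'
#' @param modifiers named list of character vectors, one per modifier, giving
#'   the substantive levels (must not contain the reserved strings).
#' @param contexts character vector of behavioural-context labels; the
#'   special labels `"unknown"` and `"other"` need not be listed.
#' @param actions optional character vector of admissible gesture-action
#'   labels (`NULL` = any label accepted).
#' @param applicability named list: for each gesture action, the character
#'   vector of applicable modifier names. Actions absent from the map are
#'   assumed to take all four modifiers.
#' @return an object of class `"morphrep_vocab"`.
#' @export
morphrep_vocab <- function(modifiers = default_modifier_levels(),
                           contexts = default_context_levels(),
                           actions = NULL,
                           applicability = list()) {
  stopifnot(is.list(modifiers), !is.null(names(modifiers)))
  reserved <- c("unclear", "not_applicable")
  for (m in names(modifiers)) {
    if (any(reserved %in% modifiers[[m]]))
      stop("modifier '", m, "' declares a reserved level string")
  }
  structure(
    list(modifiers = modifiers, contexts = contexts, actions = actions,
         applicability = applicability),
    class = "morphrep_vocab"
  )
}

#' @rdname morphrep_vocab
#' @export
default_modifier_levels <- function() {
  list(
    body_part = c("hand", "foot", "head", "mouth", "torso", "arm"),
    contact_recipient = c("contact", "no_contact"),
    lateral_use = c("left", "right", "both"),
    repetition = c("single", "repeated")
  )
}

#' @rdname morphrep_vocab
#' @export
default_context_levels <- function() {
  c("resting", "playing", "grooming", "traveling", "affiliating",
    "sexual", "carrying", "feeding", "nursing", "agonistic",
    "displaying", "object_play", "self_grooming", "vigilance", "drinking")
}

#' Names of the four gesture modifiers
#' @return character vector of modifier column names.
#' @export
modifier_names <- function() {
  c("body_part", "contact_recipient", "lateral_use", "repetition")
}

#' Applicable modifiers for one gesture action
#' @param vocab a [morphrep_vocab()] object.
#' @param action gesture-action label.
#' @return character vector of applicable modifier names.
#' @export
applicable_modifiers <- function(vocab, action) {
  map <- vocab$applicability
  if (!is.null(map[[action]])) map[[action]] else names(vocab$modifiers)
}
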