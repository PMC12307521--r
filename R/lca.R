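#' Prepare per-action modifier vectors for latent-class analysis
#'
#' Morph detection runs within each gesture action on the applicable
#' modifiers only. Tokens with an unclear applicable modifier are removed;
#' modifiers that are invariant across an action's remaining tokens are
#' dropped (they contribute a constant likelihood factor); actions left
#' with fewer than `action_min` tokens are routed to the "unspecified"
#' category and excluded from morph detection.
#'
#' @param tokens thresholded (repertoire) token table.
#' @param vocab a [morphrep_vocab()] supplying the applicability map.
#' @param action_min minimum token count for inclusion in the LCA.
#' @return list with `data` (per analyzed action: `vectors` character
#'   matrix, `token_ids`, `dropped_modifiers`), `unspecified` (data.frame
#'   action/token_count), and `report` (counts at each filter step:
#'   `n_input`, `n_unclear_excluded`, `n_subthreshold_excluded`,
#'   `n_analyzed`).
#' @export
prepare_lca_inputs <- function(tokens, vocab = morphrep_vocab(),
                               action_min = 10) {
  mods <- modifier_names()
  data <- list()
  unspecified <- list()
  n_unclear <- 0L
  n_sub <- 0L
  for (a in sort(unique(tokens$gesture_action))) {
    tk <- tokens[tokens$gesture_action == a, , drop = FALSE]
    app <- applicable_modifiers(vocab, a)
    vec <- as.matrix(tk[, app, drop = FALSE])
    clear <- rowSums(vec == "unclear") == 0
    n_unclear <- n_unclear + sum(!clear)
    vec <- vec[clear, , drop = FALSE]
    ids <- tk$token_id[clear]
    if (nrow(vec) < action_min) {
      n_sub <- n_sub + nrow(vec)
      unspecified[[a]] <- data.frame(gesture_action = a,
                                     token_count = nrow(vec),
                                     stringsAsFactors = FALSE)
      next
    }
    invariant <- vapply(seq_len(ncol(vec)),
                        function(j) length(unique(vec[, j])) == 1,
                        logical(1))
    data[[a]] <- list(vectors = vec[, !invariant, drop = FALSE],
                      token_ids = ids,
                      dropped_modifiers = colnames(vec)[invariant])
  }
  list(
    data = data,
    unspecified = if (length(unspecified)) do.call(rbind, unspecified)
      else data.frame(gesture_action = character(),
                      token_count = integer()),
    report = data.frame(
      n_input = nrow(tokens),
      n_unclear_excluded = n_unclear,
      n_subthreshold_excluded = n_sub,
      n_analyzed = nrow(tokens) - n_unclear - n_sub
    )
  )
}

# integer-encode a character matrix of modifier levels; returns codes,
# level dictionaries, and the collapse onto unique row patterns
encode_vectors <- function(vectors) {
  n <- nrow(vectors)
  m <- ncol(vectors)
  levels <- lapply(seq_len(m), function(j) sort(unique(vectors[, j])))
  names(levels) <- colnames(vectors)
  codes <- matrix(0L, n, m)
  for (j in seq_len(m))
    codes[, j] <- match(vectors[, j], levels[[j]])
  key <- if (m) apply(codes, 1, paste, collapse = "\r")
         else rep("", n)
  uk <- unique(key)
  pat_of <- match(key, uk)
  upat <- codes[match(uk, key), , drop = FALSE]
  list(codes = codes, levels = levels, pattern_of = pat_of,
       patterns = upat, weights = as.vector(table(factor(pat_of,
                                        levels = seq_along(uk)))))
}

#' Fit a multinomial latent-class model to one action's modifier vectors
#'
#' Maximizes `sum_i log sum_k pi_k prod_m p_{k,m,x_im}` by EM, taking the
#' best of `n_restarts` random starts (Dirichlet(1) initialization). The
#' log-likelihood is non-decreasing over iterations; the trace is returned
#' so that property can be asserted. With `k = 1` the maximum is closed
#' form (item responses equal the empirical marginal frequencies) and is
#' computed directly. Duplicated modifier vectors are collapsed to weighted
#' unique patterns, so runtime scales with the number of distinct
#' configurations rather than tokens.
#'
#' @param vectors character matrix: one row per token, one column per
#'   (non-invariant, applicable) modifier.
#' @param k number of latent classes (>= 1).
#' @param n_restarts random restarts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @param seed integer seed (deterministic fits).
#' @return object of class `"morphrep_lca"`: `k`, `class_weights`,
#'   `item_response` (per modifier: k x levels matrix), `log_likelihood`,
#'   `ll_trace`, `bic`, `n_obs`, `n_parameters`, `assignments` (max
#'   posterior, ties to the lower class index), `posterior` (n x k),
#'   `posterior_margin`.
#' @export
fit_lca <- function(vectors, k, n_restarts = 20, tol = 1e-8,
                    max_iter = 1000, seed = 1L) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  stopifnot(k >= 1, n >= 1)
  enc <- encode_vectors(vectors)
  u <- nrow(enc$patterns)
  if (k > u)
    stop_morphrep(paste0("k = ", k, " exceeds the ", u,
                         " distinct modifier vectors; reduce k"),
                  "morphrep_reduce_k_error")
  m <- ncol(vectors)
  L <- vapply(enc$levels, length, 1L)
  w <- enc$weights

  if (k == 1 || m == 0) {
    item <- lapply(seq_len(m), function(j) {
      tab <- tapply(w, factor(enc$patterns[, j], levels = seq_len(L[j])),
                    sum)
      tab[is.na(tab)] <- 0
      matrix(tab / n, nrow = 1, dimnames = list(NULL, enc$levels[[j]]))
    })
    names(item) <- colnames(vectors)
    ll <- sum(vapply(seq_len(m), function(j)
      sum(w * log(item[[j]][1, enc$patterns[, j]])), 0))
    post <- matrix(1, n, 1)
    fit <- list(pi = 1, item = item, ll = ll, trace = ll,
                post_pat = matrix(1, u, 1))
  } else {
    # one-hot pattern matrix: u x sum(L), blocks per modifier
    offs <- c(0L, cumsum(L))[seq_len(m)]
    X <- matrix(0, u, sum(L))
    for (j in seq_len(m))
      X[cbind(seq_len(u), offs[j] + enc$patterns[, j])] <- 1
    set.seed(seed)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      cand <- em_once(X, w, k, L, offs, tol, max_iter)
      if (is.null(best) || cand$ll > best$ll) best <- cand
    }
    fit <- best
    fit$item <- lapply(seq_len(m), function(j) {
      blk <- fit$theta[, offs[j] + seq_len(L[j]), drop = FALSE]
      colnames(blk) <- enc$levels[[j]]
      blk
    })
    names(fit$item) <- colnames(vectors)
    post <- fit$post_pat[enc$pattern_of, , drop = FALSE]
  }

  d <- (k - 1) + k * sum(L - 1)
  assign <- max.col(post, ties.method = "first")
  margin <- apply(post, 1, function(p) {
    s <- sort(p, decreasing = TRUE)
    if (length(s) > 1) s[1] - s[2] else 1
  })
  structure(list(
    k = k, class_weights = fit$pi, item_response = fit$item,
    log_likelihood = fit$ll, ll_trace = fit$trace,
    bic = -2 * fit$ll + d * log(n), n_obs = n, n_parameters = d,
    n_distinct = u, assignments = assign, posterior = post,
    posterior_margin = margin, modifiers = colnames(vectors)
  ), class = "morphrep_lca")
}

# one EM run on weighted unique patterns; X is the u x sum(L) one-hot
# matrix, theta the k x sum(L) item-response matrix (blocks per modifier)
em_once <- function(X, w, k, L, offs, tol, max_iter) {
  u <- nrow(X)
  m <- length(L)
  n <- sum(w)
  rdir <- function(len) { g <- -log(stats::runif(len)); g / sum(g) }
  pi_k <- rdir(k)
  theta <- matrix(0, k, sum(L))
  for (kk in seq_len(k)) for (j in seq_len(m))
    theta[kk, offs[j] + seq_len(L[j])] <- rdir(L[j])
  ll_old <- -Inf
  trace <- numeric(max_iter)
  it <- 0L
  repeat {
    it <- it + 1L
    # E step: log p(pattern | class) = X %*% log theta'
    lp <- X %*% t(log(pmax(theta, 1e-300)))
    lp <- sweep(lp, 2, log(pi_k), `+`)
    lse <- logsumexp_rows(lp)
    ll <- sum(w * lse)
    trace[it] <- ll
    resp <- exp(lp - lse)
    # M step
    W <- w * resp
    wk <- colSums(W)
    pi_k <- wk / n
    theta <- crossprod(W, X) / wk
    if (it >= max_iter ||
        (is.finite(ll_old) && (ll - ll_old) <= tol * abs(ll_old))) break
    ll_old <- ll
  }
  list(pi = pi_k, theta = theta, ll = ll, trace = trace[seq_len(it)],
       post_pat = resp)
}

#' Select the number of latent classes by BIC
#'
#' Fits k = 1..min(`k_max`, number of distinct vectors) and returns the
#' minimum-BIC model, `BIC = -2 LL + d log n` with
#' `d = (k - 1) + k * sum_m (L_m - 1)`; ties go to the smaller k.
#'
#' @inheritParams fit_lca
#' @param k_max largest class count to consider.
#' @return the selected `"morphrep_lca"` model.
#' @export
select_model <- function(vectors, k_max = 8, n_restarts = 20, tol = 1e-8,
                         max_iter = 1000, seed = 1L) {
  vectors <- as.matrix(vectors)
  u <- if (ncol(vectors) == 0) 1L else nrow(unique(vectors))
  best <- NULL
  for (k in seq_len(min(k_max, u))) {
    fit <- fit_lca(vectors, k, n_restarts = n_restarts, tol = tol,
                   max_iter = max_iter, seed = seed + k)
    if (is.null(best) || fit$bic < best$bic - 1e-9) best <- fit
  }
  best
}

#' Derive morphs from a fitted latent-class model
#'
#' Tokens are hard-assigned to their maximum-posterior class (ties to the
#' lower class index). Classes with fewer than `morph_min` assigned tokens
#' are not morphs; their tokens are reported as unassigned. Surviving
#' classes are renumbered by descending size and labelled
#' `"<action>.<i>_<K>"` where `K` is the number of morphs of that action.
#' Each morph's modal configuration (most probable level per modifier) is
#' reported.
#'
#' @param model a `"morphrep_lca"` fit.
#' @param action gesture-action label used in morph ids.
#' @param morph_min minimum assigned tokens for a class to count as a morph.
#' @param token_ids optional token identifiers (parallel to the fitted
#'   rows) recorded per morph and for the unassigned set.
#' @return list: `morphs` (data.frame `morph_id`, `class_index`,
#'   `token_count`, one `modal_*` column per modifier), `unassigned`
#'   (token ids, possibly empty), `assignment` (per-token morph id or NA).
#' @export
derive_morphs <- function(model, action, morph_min = 5,
                          token_ids = NULL) {
  stopifnot(inherits(model, "morphrep_lca"))
  if (is.null(token_ids)) token_ids <- as.character(seq_len(model$n_obs))
  sizes <- tabulate(model$assignments, nbins = model$k)
  keep <- which(sizes >= morph_min)
  keep <- keep[order(-sizes[keep], keep)]
  K <- length(keep)
  assignment <- rep(NA_character_, model$n_obs)
  morphs <- NULL
  if (K > 0) {
    modal <- lapply(model$item_response, function(ir)
      colnames(ir)[max.col(ir, ties.method = "first")])
    rows <- lapply(seq_len(K), function(i) {
      cls <- keep[i]
      row <- data.frame(morph_id = sprintf("%s.%d_%d", action, i, K),
                        class_index = cls, token_count = sizes[cls],
                        stringsAsFactors = FALSE)
      for (mname in model$modifiers)
        row[[paste0("modal_", mname)]] <- modal[[mname]][cls]
      row
    })
    morphs <- do.call(rbind, rows)
    for (i in seq_len(K))
      assignment[model$assignments == keep[i]] <- morphs$morph_id[i]
  }
  list(
    morphs = morphs %||% data.frame(morph_id = character(),
                                    class_index = integer(),
                                    token_count = integer()),
    unassigned = token_ids[is.na(assignment)],
    assignment = stats::setNames(assignment, token_ids)
  )
}

#' Run morph detection across all analyzable actions
#'
#' Applies [select_model()] and [derive_morphs()] to every action retained
#' by [prepare_lca_inputs()].
#'
#' @param prepared result of [prepare_lca_inputs()].
#' @param k_max,n_restarts,tol,max_iter,seed passed to [select_model()]
#'   (per-action seeds are derived from `seed`).
#' @param morph_min minimum tokens per morph.
#' @return list of per-action results (`model`, `morphs`, `unassigned`,
#'   `assignment`) plus the `unspecified` table and filter `report`.
#' @export
detect_morphs <- function(prepared, k_max = 8, morph_min = 5,
                          n_restarts = 20, tol = 1e-8, max_iter = 1000,
                          seed = 1L) {
  res <- list()
  acts <- names(prepared$data)
  for (i in seq_along(acts)) {
    a <- acts[i]
    d <- prepared$data[[a]]
    model <- select_model(d$vectors, k_max = k_max,
                          n_restarts = n_restarts, tol = tol,
                          max_iter = max_iter, seed = seed + 101L * i)
    dm <- derive_morphs(model, action = a, morph_min = morph_min,
                        token_ids = d$token_ids)
    res[[a]] <- list(model = model, morphs = dm$morphs,
                     unassigned = dm$unassigned,
                     assignment = dm$assignment)
  }
  list(actions = res, unspecified = prepared$unspecified,
       report = prepared$report)
}

#' Summarize a morph repertoire
#'
#' Classifies analyzed actions as unimorphic (one morph) or polymorphic
#' (two or more), carries the unspecified actions (in the repertoire but
#' below the LCA threshold), and totals the repertoire units: unimorphic
#' actions + morphs of polymorphic actions + unspecified actions. Also
#' reports the distribution of morphs per polymorphic action and the
#' fraction of analyzed tokens left unassigned (classes below the morph
#' threshold).
#'
#' @param detection result of [detect_morphs()].
#' @return list of class `"morphrep_morphsum"`: counts, `morph_table`
#'   (all morphs), `mean_morphs_per_polymorphic` (absent with zero
#'   polymorphic actions), `sd_morphs`, `range_morphs`,
#'   `unassigned_fraction`, `action_classes`.
#' @export
summarize_morph_repertoire <- function(detection) {
  res <- detection$actions
  n_morphs <- vapply(res, function(r) nrow(r$morphs), 1L)
  uni <- names(res)[n_morphs == 1]
  poly <- names(res)[n_morphs >= 2]
  unresolved <- names(res)[n_morphs == 0]
  morph_table <- do.call(rbind, c(lapply(res, function(r)
    r$morphs[, c("morph_id", "token_count")]), make.row.names = FALSE))
  n_unassigned <- sum(vapply(res, function(r) length(r$unassigned), 1L))
  n_analyzed <- sum(vapply(res, function(r) as.numeric(r$model$n_obs),
                           numeric(1)))
  per_poly <- n_morphs[poly]
  n_unspec <- nrow(detection$unspecified)
  structure(list(
    n_unimorphic = length(uni),
    n_polymorphic = length(poly),
    n_unresolved = length(unresolved),
    n_unspecified = n_unspec,
    n_polymorphic_morphs = sum(per_poly),
    n_units = length(uni) + sum(per_poly) + n_unspec,
    mean_morphs_per_polymorphic = if (length(poly)) mean(per_poly) else NA,
    sd_morphs = if (length(poly) > 1) stats::sd(per_poly) else NA,
    range_morphs = if (length(poly)) range(per_poly) else NULL,
    unassigned_fraction = if (n_analyzed) n_unassigned / n_analyzed else NA,
    n_analyzed_actions = length(res),
    n_analyzed_tokens = n_analyzed,
    morph_table = morph_table,
    action_classes = list(unimorphic = uni, polymorphic = poly,
                          unresolved = unresolved,
                          unspecified = detection$unspecified$gesture_action)
  ), class = "morphrep_morphsum")
}
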