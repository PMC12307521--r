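test_that("LCA inputs: unclear removal, invariant dropping, unspecified routing", {
  tok <- toy_tokens(rep(c("A", "B"), c(12, 9)))
  tok$lateral_use <- "right"                      # invariant everywhere
  tok$body_part[1] <- "unclear"
  prep <- prepare_lca_inputs(tok, action_min = 10)
  expect_identical(names(prep$data), "A")
  expect_identical(nrow(prep$data$A$vectors), 11L)      # 12 - 1 unclear
  expect_false("lateral_use" %in% colnames(prep$data$A$vectors))
  expect_true("lateral_use" %in% prep$data$A$dropped_modifiers)
  expect_identical(prep$unspecified$gesture_action, "B")  # 9 < 10
  expect_identical(prep$report$n_analyzed, 11L)
  expect_identical(prep$report$n_unclear_excluded, 1L)
  expect_identical(prep$report$n_subthreshold_excluded, 9L)

  # unclear in a non-applicable modifier does not exclude the token
  vocab <- morphrep_vocab(applicability =
                            list(A = c("body_part", "repetition")))
  tok2 <- toy_tokens(rep("A", 12))
  tok2$lateral_use[3] <- "unclear"
  tok2$body_part <- rep(c("hand", "foot"), 6)
  prep2 <- prepare_lca_inputs(tok2, vocab, action_min = 10)
  expect_identical(nrow(prep2$data$A$vectors), 12L)
})

test_that("k = 1 fit equals the closed-form independent-multinomial solution", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    vec <- cbind(
      body_part = sample(c("hand", "foot", "head"), n, TRUE),
      repetition = sample(c("single", "repeated"), n, TRUE)
    )
    fit <- fit_lca(vec, k = 1, seed = rep)
    # item responses are the empirical marginals, exactly
    for (m in colnames(vec)) {
      emp <- table(vec[, m]) / n
      expect_equal(fit$item_response[[m]][1, names(emp)], c(emp),
                   tolerance = 1e-12)
    }
    ll_closed <- sum(vapply(colnames(vec), function(m) {
      cnt <- table(vec[, m])
      sum(cnt * log(cnt / n))
    }, 0))
    expect_equal(fit$log_likelihood, ll_closed, tolerance = 1e-10)
    expect_true(all(fit$assignments == 1))
  }
})

test_that("identical vectors give a degenerate single class", {
  vec <- planted_vectors(list(config = c(body_part = "hand",
                                         repetition = "single"),
                              count = 30))
  fit <- fit_lca(vec, 1)
  expect_equal(unname(fit$class_weights), 1)
  expect_equal(unname(fit$item_response$body_part[1, "hand"]), 1)
  expect_equal(fit$log_likelihood, 0)
  expect_error(fit_lca(vec, 2), class = "morphrep_reduce_k_error")
})

test_that("two well-separated components are recovered with equal weights", {
  vec <- planted_vectors(
    list(config = c(body_part = "hand", contact_recipient = "contact"),
         count = 20),
    list(config = c(body_part = "foot", contact_recipient = "no_contact"),
         count = 20))
  fit <- fit_lca(vec, 2, seed = 7)
  expect_equal(sort(unname(fit$class_weights)), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_identical(length(unique(fit$assignments[1:20])), 1L)
  expect_identical(length(unique(fit$assignments[21:40])), 1L)
  expect_false(fit$assignments[1] == fit$assignments[21])
  sel <- select_model(vec, seed = 3)
  expect_identical(sel$k, 2L)
})

test_that("EM log-likelihood is non-decreasing and deterministic given seed", {
  set.seed(99)
  vec <- cbind(body_part = sample(c("hand", "foot", "mouth"), 80, TRUE),
               lateral_use = sample(c("left", "right"), 80, TRUE))
  f1 <- fit_lca(vec, 3, n_restarts = 5, seed = 11)
  f2 <- fit_lca(vec, 3, n_restarts = 5, seed = 11)
  expect_identical(f1[c("class_weights", "item_response",
                        "log_likelihood", "assignments")],
                   f2[c("class_weights", "item_response",
                        "log_likelihood", "assignments")])
  expect_true(all(diff(f1$ll_trace) >= -1e-8))
  expect_lte(f1$log_likelihood, 0)
})

test_that("model selection picks k = 1 for single-configuration data", {
  vec <- planted_vectors(list(config = c(body_part = "hand",
                                         lateral_use = "left"),
                              count = 25))
  expect_identical(select_model(vec)$k, 1L)
})

test_that("BIC selects the planted k = 3 at epsilon 0.02 in at least 9/10 seeds", {
  lv <- default_modifier_levels()
  tab <- morphrep:::component_table()[1:3, ]
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n_per <- c(80, 70, 50)    # n = 200
    vec <- tab[rep(1:3, n_per), ]
    for (m in colnames(vec)) {
      flip <- stats::runif(200) < 0.02
      vec[flip, m] <- vapply(vec[flip, m], function(x)
        sample(setdiff(lv[[m]], x), 1), "")
    }
    sel <- select_model(vec, seed = seed + 100)
    hits <- hits + (sel$k == 3)
  }
  expect_gte(hits, 9)
})

test_that("morph derivation applies the size threshold, naming and conservation", {
  # k = 1: one morph covering everything
  vec1 <- planted_vectors(list(config = c(body_part = "hand",
                                          repetition = "single"),
                               count = 30))
  m1 <- derive_morphs(fit_lca(vec1, 1), action = "touch")
  expect_identical(m1$morphs$morph_id, "touch.1_1")
  expect_identical(m1$morphs$token_count, 30L)
  expect_identical(length(m1$unassigned), 0L)

  # class sizes 26 and 4: the small class is dissolved, tokens unassigned
  vec2 <- planted_vectors(
    list(config = c(body_part = "hand", contact_recipient = "contact"),
         count = 26),
    list(config = c(body_part = "foot", contact_recipient = "no_contact"),
         count = 4))
  fit2 <- fit_lca(vec2, 2, seed = 3)
  m2 <- derive_morphs(fit2, action = "grab", morph_min = 5)
  expect_identical(nrow(m2$morphs), 1L)
  expect_identical(m2$morphs$morph_id, "grab.1_1")
  expect_identical(m2$morphs$token_count, 26L)
  expect_identical(length(m2$unassigned), 4L)
  expect_identical(m2$morphs$token_count + length(m2$unassigned),
                   fit2$n_obs)

  # three morphs: suffixes .1_3 .2_3 .3_3 ordered by size
  vec3 <- planted_vectors(
    list(config = c(body_part = "hand", lateral_use = "left",
                    repetition = "single"), count = 20),
    list(config = c(body_part = "foot", lateral_use = "right",
                    repetition = "repeated"), count = 12),
    list(config = c(body_part = "mouth", lateral_use = "both",
                    repetition = "single"), count = 8))
  m3 <- derive_morphs(fit_lca(vec3, 3, seed = 5), action = "push")
  expect_identical(m3$morphs$morph_id,
                   c("push.1_3", "push.2_3", "push.3_3"))
  expect_identical(m3$morphs$token_count, c(20L, 12L, 8L))
})

test_that("class relabeling leaves BIC, partition and morphs unchanged", {
  vec <- planted_vectors(
    list(config = c(body_part = "hand", contact_recipient = "contact"),
         count = 18),
    list(config = c(body_part = "foot", contact_recipient = "no_contact"),
         count = 9))
  fit <- fit_lca(vec, 2, seed = 2)
  perm <- fit
  perm$class_weights <- fit$class_weights[2:1]
  perm$item_response <- lapply(fit$item_response, function(ir)
    ir[2:1, , drop = FALSE])
  perm$posterior <- fit$posterior[, 2:1]
  perm$assignments <- 3L - fit$assignments
  d <- (fit$k - 1) + fit$k * sum(vapply(fit$item_response, ncol, 1L) - 1)
  expect_equal(-2 * perm$log_likelihood + d * log(perm$n_obs), fit$bic)
  m_orig <- derive_morphs(fit, "a")
  m_perm <- derive_morphs(perm, "a")
  expect_identical(m_orig$morphs[, c("morph_id", "token_count")],
                   m_perm$morphs[, c("morph_id", "token_count")])
  expect_identical(unname(m_orig$assignment), unname(m_perm$assignment))
})

test_that("exact recovery of planted partitions at epsilon 0 (grouping oracle)", {
  cfg <- bwindi_config(epsilon = 0)
  d <- generate_dataset(cfg, seed = 17)
  thr <- apply_repertoire_threshold(d$tokens, 3)
  prep <- prepare_lca_inputs(thr$tokens, cfg$vocab, 10)
  det <- detect_morphs(prep, seed = 18)
  truth <- d$truth
  for (a in names(det$actions)[1:12]) {
    r <- det$actions[[a]]
    ids <- prep$data[[a]]$token_ids
    planted <- truth$component[match(ids, truth$token_id)]
    got <- r$assignment[ids]
    # same partition: one-to-one between planted components and morphs
    expect_identical(length(r$unassigned), 0L)
    tab <- table(planted, got)
    expect_true(all(rowSums(tab > 0) == 1), label = a)
    expect_true(all(colSums(tab > 0) == 1), label = a)
  }
})

test_that("morph repertoire summary totals and categories are consistent", {
  mk_res <- function(n_morphs, n_obs = 40) {
    morphs <- if (n_morphs > 0)
      data.frame(morph_id = sprintf("x.%d_%d", seq_len(n_morphs), n_morphs),
                 token_count = rep(10, n_morphs))
    else data.frame(morph_id = character(), token_count = integer())
    list(model = structure(list(n_obs = n_obs), class = "morphrep_lca"),
         morphs = morphs, unassigned = character(), assignment = NULL)
  }
  det <- list(actions = list(a = mk_res(1), b = mk_res(1), c = mk_res(2),
                             d = mk_res(3)),
              unspecified = data.frame(gesture_action = "e",
                                       token_count = 5))
  s <- summarize_morph_repertoire(det)
  expect_identical(s$n_unimorphic, 2L)
  expect_identical(s$n_polymorphic, 2L)
  expect_identical(s$n_unspecified, 1L)
  expect_identical(s$n_units, 2L + 5L + 1L)
  expect_equal(s$mean_morphs_per_polymorphic, 2.5)

  det0 <- list(actions = list(a = mk_res(1)),
               unspecified = data.frame(gesture_action = character(),
                                        token_count = integer()))
  s0 <- summarize_morph_repertoire(det0)
  expect_true(is.na(s0$mean_morphs_per_polymorphic))
})
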