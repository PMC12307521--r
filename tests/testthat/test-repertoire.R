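test_that("repertoire threshold removes rare actions with their tokens", {
  tok <- toy_tokens(rep(c("A", "B", "C"), c(5, 2, 1)))
  out <- apply_repertoire_threshold(tok, 3)
  expect_identical(out$actions, "A")
  expect_identical(nrow(out$tokens), 5L)
  expect_identical(out$excluded$gesture_action, c("B", "C"))
  expect_identical(out$excluded$token_count, c(2L, 1L))

  # all actions at or above the threshold: identity
  tok2 <- toy_tokens(rep(c("A", "B"), c(3, 4)))
  out2 <- apply_repertoire_threshold(tok2, 3)
  expect_identical(out2$tokens, tok2)
  expect_identical(nrow(out2$excluded), 0L)

  # empty input is not an error
  out3 <- apply_repertoire_threshold(tok[0, ], 3)
  expect_identical(nrow(out3$tokens), 0L)
})

test_that("contribution table matches hand-computed percentages and deviations", {
  tok <- toy_tokens(rep(c("A", "B", "C"), c(6, 3, 1)))
  ct <- build_contribution_table(tok)
  expect_identical(ct$gesture_action, c("A", "B", "C"))
  expect_equal(ct$contribution_pct, c(60.0, 30.0, 10.0))
  expect_equal(ct$cumulative_pct, c(60.0, 90.0, 100.0))
  expect_equal(attr(ct, "average_contribution_raw"), 10 / 3,
               tolerance = 1e-12)
  # deviations from 3.33: +2.67, -0.33, -2.33 -> +3 / 0 / -2
  expect_equal(ct$deviation_from_average, c(3, 0, -2))

  single <- build_contribution_table(toy_tokens(rep("A", 10)))
  expect_equal(single$contribution_pct, 100.0)
  expect_equal(single$cumulative_pct, 100.0)
  expect_equal(single$deviation_from_average, 0)

  expect_error(build_contribution_table(tok[0, ]),
               class = "morphrep_empty_error")
})

test_that("contribution invariants hold on generated data", {
  d <- generate_dataset(bwindi_config(), seed = 8)
  ct <- build_contribution_table(apply_repertoire_threshold(d$tokens,
                                                            3)$tokens)
  n_act <- nrow(ct)
  expect_lt(abs(sum(ct$contribution_pct) - 100), 0.05 * n_act)
  expect_true(all(diff(ct$cumulative_pct) >= -1e-9))
  expect_lt(abs(sum(ct$deviation_from_average)), n_act / 2)
  expect_identical(sum(ct$token_count), nrow(d$tokens) - 17L)
})

test_that("regular-use set is the minimal prefix reaching the target share", {
  tok <- toy_tokens(rep(c("A", "B", "C"), c(60, 30, 10)))
  ct <- build_contribution_table(tok)
  expect_identical(regular_use_set(ct, 0.695), c("A", "B"))
  expect_identical(regular_use_set(ct, 0.6), "A")
  expect_identical(regular_use_set(ct, 1), c("A", "B", "C"))
  expect_error(regular_use_set(ct, 0), class = "morphrep_parameter_error")
  expect_error(regular_use_set(ct, 1.2), class = "morphrep_parameter_error")

  single <- build_contribution_table(toy_tokens(rep("A", 4)))
  expect_identical(regular_use_set(single, 0.01), "A")

  # lowering the target never enlarges the set
  sizes <- vapply(seq(0.05, 1, by = 0.05),
                  function(f) length(regular_use_set(ct, f)), 1L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("accumulation curve counts first occurrences in order", {
  tok <- toy_tokens(c("A", "B", "A", "C"))
  acc <- accumulation_curve(tok, "action")
  expect_equal(acc$points$units, c(1, 2, 2, 3))
  expect_identical(acc$last_novelty_index, 4L)
  expect_equal(acc$last_novelty_fraction, 1)

  one <- accumulation_curve(toy_tokens(rep("A", 5)), "action")
  expect_true(all(one$points$units == 1))
  expect_identical(one$last_novelty_index, 1L)

  # invariant to token metadata, dependent only on first-occurrence order
  tok2 <- tok
  tok2$signaller_id <- rev(tok2$signaller_id)
  expect_identical(accumulation_curve(tok2, "action")$points, acc$points)

  expect_error(accumulation_curve(tok, "unit"),
               class = "morphrep_parameter_error")
  expect_error(accumulation_curve(tok, "morph"),
               class = "morphrep_parameter_error")
})

test_that("permutation envelope mean equals the exhaustive rarefaction expectation", {
  # counts {A:2, B:1, C:1}: enumerate all 4!/2! = 12 distinct orderings
  units <- c("A", "A", "B", "C")
  perms <- unique(combinat_permutations(units))
  exact <- Reduce(`+`, lapply(perms, function(p)
    cumsum(!duplicated(p)))) / length(perms)
  # analytic rarefaction: E[S(t)] = sum_a 1 - choose(n - n_a, t)/choose(n, t)
  n <- 4
  na <- c(A = 2, B = 1, C = 1)
  analytic <- vapply(1:4, function(t)
    sum(1 - choose(n - na, t) / choose(n, t)), 0)
  expect_equal(exact, analytic, tolerance = 1e-12)

  tok <- toy_tokens(units)
  acc <- accumulation_curve(tok, "action", n_permutations = 4000, seed = 2)
  expect_equal(acc$envelope$mean, analytic, tolerance = 0.05)
})

test_that("overall rate divides tokens by unique group-season follow hours", {
  tok <- toy_tokens(rep("A", 12))
  eff <- toy_effort(follow = 24)  # two members share the same 24 h
  expect_equal(overall_rate(tok, eff), 0.5)
  expect_equal(overall_rate(tok[0, ], eff), 0)
  eff0 <- toy_effort(follow = 0)
  expect_error(overall_rate(tok, eff0), class = "morphrep_parameter_error")
})
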