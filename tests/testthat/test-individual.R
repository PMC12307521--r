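test_that("maturation rules cover the age/sex/parity boundaries", {
  cases <- list(
    list(2, "male", FALSE, "cat1_infant"),
    list(3, "female", FALSE, "cat1_infant"),
    list(3.1, "male", FALSE, "cat2_juvenile"),
    list(6, "female", FALSE, "cat2_juvenile"),
    list(7, "female", FALSE, "cat3_subadult_blackback_nulliparous"),
    list(7, "male", FALSE, "cat3_subadult_blackback_nulliparous"),
    list(10, "male", FALSE, "cat3_subadult_blackback_nulliparous"),  # blackback
    list(10, "female", FALSE, "cat3_subadult_blackback_nulliparous"),
    list(12.5, "male", FALSE, "cat4_adult"),
    list(12, "female", FALSE, "cat4_adult"),      # nulliparous >= 12
    list(21, "female", FALSE, "cat4_adult"),      # adult despite nulliparity
    list(9, "female", TRUE, "cat4_adult")         # parity overrides age
  )
  for (cs in cases)
    expect_identical(maturation_class(cs[[1]], cs[[2]], cs[[3]]), cs[[4]],
                     label = paste(cs[[1]], cs[[2]], cs[[3]]))
  expect_error(maturation_class(-1, "male"),
               class = "morphrep_parameter_error")
  expect_error(maturation_class(5, "unknown"),
               class = "morphrep_parameter_error")
})

test_that("within-season boundary crossing resolves to the majority class", {
  seasons <- bwindi_seasons()
  s1 <- seasons[1, ]
  # male crossing 3.0 years during s1 (born 2019-07-15)
  ind <- data.frame(individual_id = "x", sex = "male",
                    birth_date = "2019-07-15", parity_events = "",
                    groups = "g:s1", stringsAsFactors = FALSE)
  before <- c(cat1_infant = 7, cat2_juvenile = 2)
  a <- assign_maturation_class(ind, s1, token_class_counts = before)
  expect_identical(a$class, "cat1_infant")
  after <- c(cat1_infant = 2, cat2_juvenile = 7)
  b <- assign_maturation_class(ind, s1, token_class_counts = after)
  expect_identical(b$class, "cat2_juvenile")

  # first birth late in a season still makes the female parous for it
  mother <- data.frame(individual_id = "m", sex = "female",
                       birth_date = "2012-01-01",
                       parity_events = "2022-08-25",  # near s1 end
                       groups = "g:s1", stringsAsFactors = FALSE)
  expect_identical(assign_maturation_class(mother, s1)$class, "cat4_adult")
  # and not parous in a season that closed before the birth
  early <- data.frame(individual_id = "m2", sex = "female",
                      birth_date = "2012-01-01",
                      parity_events = "2023-08-01",
                      groups = "g:s1", stringsAsFactors = FALSE)
  expect_identical(assign_maturation_class(early, s1)$class,
                   "cat3_subadult_blackback_nulliparous")
})

test_that("IRS counts distinct actions at the signaller threshold", {
  tok <- toy_tokens(rep(c("A", "B", "C"), c(3, 1, 5)))
  expect_identical(unname(compute_irs(tok, 1)), 3L)
  expect_identical(unname(compute_irs(tok, 3)), 2L)

  tok2 <- toy_tokens(c("A", "A"))
  expect_identical(unname(compute_irs(tok2, 1)), 1L)
  expect_identical(unname(compute_irs(tok2, 3)), 0L)

  expect_error(compute_irs(tok, 1, signallers = "nobody"),
               class = "morphrep_parameter_error")
})

test_that("IGR is tokens per presence-summed hour; zero denominators are NA", {
  tok <- toy_tokens(rep("A", 12))
  eff <- toy_effort(ids = "ind1", follow = 24, video = 6)
  g <- compute_igr(tok, eff)
  expect_equal(g$igr_obs, 0.5)
  expect_equal(g$igr_vid, 2)

  none <- compute_igr(tok[0, ], eff, signallers = "ind1")
  expect_equal(none$igr_obs, 0)

  eff0 <- toy_effort(ids = "ind1", follow = 0, video = 0)
  g0 <- compute_igr(tok, eff0)
  expect_true(is.na(g0$igr_obs))
  expect_true(is.na(g0$igr_vid))
})

test_that("IRS invariants: irs_3 <= irs_1, monotone under augmentation", {
  cfg <- toy_synth_config(epsilon = 0.05)
  d <- generate_dataset(cfg, seed = 6)
  s <- individual_summaries(d$tokens, d$effort)
  expect_true(all(s$irs_3 <= s$irs_1))
  expect_true(all(s$irs_1 <= s$token_count))
  half <- individual_summaries(d$tokens[1:25, ], d$effort)
  both <- intersect(half$individual_id, s$individual_id)
  expect_true(all(s$irs_1[match(both, s$individual_id)] >=
                    half$irs_1[match(both, half$individual_id)]))
})

test_that("class summaries count one data point per class occupied", {
  seasons <- bwindi_seasons()
  inds <- data.frame(
    individual_id = c("ad", "juv", "cross"),
    sex = c("female", "male", "male"),
    # cross is 2.87 at s1 midpoint, 3.37 at s2: moves cat1 -> cat2
    birth_date = c("2005-01-01", "2018-06-01", "2019-08-20"),
    parity_events = c("2020-01-01", "", ""),
    groups = "g1:s1;g1:s2", stringsAsFactors = FALSE)
  assn <- assign_maturation_classes(inds, seasons[1:2, ])
  expect_identical(nrow(assn), 6L)
  expect_identical(sum(assn$individual_id == "cross" &
                         assn$class == "cat1_infant"), 1L)

  tok <- toy_tokens(rep(c("A", "B"), 6),
                    signaller_id = rep(c("ad", "juv", "cross"), each = 4),
                    recipient_id = "other",
                    season_id = rep(c("s1", "s2"), 6))
  eff <- rbind(toy_effort(c("ad", "juv", "cross")),
               within(toy_effort(c("ad", "juv", "cross")),
                      season_id <- "s2"))
  bc <- summarize_by_class(tok, eff, assn)
  # ad -> 1 point, juv -> 1 point, cross -> 2 points (cat1 in s1, cat2 in s2)
  expect_identical(nrow(bc$points), 4L)
  n_multi <- 1L
  expect_identical(nrow(bc$points), nrow(inds) + n_multi)

  two <- bc$points[bc$points$individual_id == "cross", ]
  expect_setequal(two$class, c("cat1_infant", "cat2_juvenile"))

  # mean/range arithmetic on a two-individual class
  pts <- bc$points
  cls <- pts$class[pts$individual_id == "ad"]
  sel <- bc$summary$class == cls & bc$summary$sex == "female"
  expect_equal(bc$summary$irs_1_mean[sel],
               mean(pts$irs_1[pts$class == cls & pts$sex == "female"]))
})
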