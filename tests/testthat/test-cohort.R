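test_that("well-parameterized learners test above the chance band", {
  cards <- card_set()
  band <- chance_range(100)
  withr::with_seed(83, {
    above <- vapply(1:120, function(i) {
      p <- learner_params(learning_rate = 0.05, temperature = 0.02,
                         temperature_sd = 0, lapse_prob = 0)
      log <- simulate_participant(p, cards)
      test <- log[log$phase == "test", ]
      sum(!is.na(test$response) & test$response == test$optimal) > band[["hi"]]
    }, logical(1))
  })
  expect_gt(mean(above), 0.95)
})

test_that("non-learners score at chance at the expected rate", {
  cards <- card_set()
  band <- chance_range(100)
  # learning_rate -> 0 is disallowed by construction; a guessing learner is
  # temperature -> infinity (choice probability 0.5 everywhere)
  withr::with_seed(89, {
    at_chance <- vapply(1:400, function(i) {
      p <- learner_params(learning_rate = 0.05, temperature = 1e6,
                         temperature_sd = 0, lapse_prob = 0)
      log <- simulate_participant(p, cards)
      test <- log[log$phase == "test", ]
      k <- sum(!is.na(test$response) & test$response == test$optimal)
      k >= band[["lo"]] && k <= band[["hi"]]
    }, logical(1))
  })
  # exact binomial coverage of the band at p = 0.5
  coverage <- pbinom(band[["hi"]], 100, 0.5) - pbinom(band[["lo"]] - 1, 100, 0.5)
  expect_equal(mean(at_chance), coverage, tolerance = 0.05)
})

test_that("simulated participants are pure functions of the seed", {
  p <- learner_params()
  a <- simulate_participant(p, seed = 13)
  b <- simulate_participant(p, seed = 13)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("DIRECT injection realizes targets to trial resolution", {
  withr::with_seed(97, {
    for (i in 1:25) {
      log <- make_test_log(100, k_correct = sample(60:85, 1),
                           seed = 500 + i)
      inj <- inject_retest_effect(log, delta_mean = rnorm(1, -6, 12),
                                  delta_sd = 0)
      s2 <- score_test(inj$log, default_combos)
      s1 <- score_test(log, default_combos)
      realized <- 100 * (s2$adjusted - s1$adjusted)
      expect_equal(realized, inj$realized, tolerance = 1e-9)
      if (!inj$truncated) {
        expect_lte(abs(inj$realized - inj$target), 2 + 1e-9)
      }
    }
  })
  # zero effect: identical score; huge effect: truncation flag
  log <- make_test_log(100, 75, seed = 3)
  none <- inject_retest_effect(log, delta_mean = 0, delta_sd = 0, seed = 1)
  expect_equal(score_test(none$log, default_combos)$n_correct, 75)
  big <- inject_retest_effect(log, delta_mean = -200, delta_sd = 0, seed = 1)
  expect_true(big$truncated)
  expect_equal(score_test(big$log, default_combos)$n_correct, 0)
})

test_that("universal reversal is caught and repaired end to end", {
  cfg <- cohort_config(n_total = 12, seed = 5,
                       learner = learner_params(reversal_prob = 1),
                       group_effects = dplyr::bind_rows(lapply(
                         c("-R-I", "-R+I", "+R-I", "+R+I"), group_effect)),
                       protocol_phases = FALSE)
  sim <- simulate_cohort(cfg)
  scored <- score_cohort(sim$logs, combination_table(cfg$card_sets))
  flags <- scored$scores |>
    dplyr::filter(phase %in% c("test", "retest")) |>
    dplyr::left_join(sim$truth[, c("participant_id", "type")],
                     by = "participant_id")
  # every above-chance session that was recorded reversed must be repaired
  reversed_sessions <- dplyr::bind_rows(
    dplyr::filter(flags, phase == "test",
                  participant_id %in%
                    sim$truth$participant_id[sim$truth$reversed_test]),
    dplyr::filter(flags, phase == "retest",
                  participant_id %in%
                    sim$truth$participant_id[sim$truth$reversed_retest])
  )
  strong <- dplyr::filter(reversed_sessions, !at_chance)
  expect_gt(nrow(strong), 0)
  expect_true(all(strong$repaired))
})

test_that("cohort simulation is reproducible and size-balanced", {
  cfg <- cohort_config(n_total = 11, seed = 21, protocol_phases = FALSE)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(as.data.frame(a$logs), as.data.frame(b$logs))
  expect_identical(a$truth$group, b$truth$group)
  sizes <- table(a$assignments$group)
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("special participant types surface in scoring as injected", {
  cfg <- cohort_config(
    n_total = 16, seed = 31,
    special = c(low_compliance = 2, at_chance = 3, reversed = 2),
    protocol_phases = FALSE)
  sim <- simulate_cohort(cfg)
  scored <- score_cohort(sim$logs, combination_table(cfg$card_sets))
  excl <- apply_exclusions(scored$scores, scored$compliance)
  smry <- exclusion_summary(excl, scored$scores)
  expect_equal(smry$n_low_compliance, 2)
  expect_equal(smry$n_at_chance, 3)
  expect_equal(smry$n_repaired, 2)
  # the reversed participants repair to above-chance and stay retained
  rev_ids <- sim$truth$participant_id[sim$truth$type == "reversed"]
  expect_false(any(excl$excluded[excl$participant_id %in% rev_ids]))
})

test_that("protocol phases appear for the right groups", {
  cfg <- cohort_config(n_total = 8, seed = 41, protocol_phases = TRUE)
  sim <- simulate_cohort(cfg)
  phases <- sim$logs |>
    dplyr::distinct(participant_id, phase) |>
    dplyr::left_join(sim$truth[, c("participant_id", "group")],
                     by = "participant_id")
  has <- function(g, ph) {
    ids <- phases$participant_id[phases$group == g]
    any(phases$phase[phases$participant_id %in% ids] == ph)
  }
  expect_true(has("+R+I", "reactivation"))
  expect_true(has("+R+I", "interference_training"))
  expect_true(has("+R+I", "interference_test"))
  expect_false(has("-R-I", "reactivation"))
  expect_false(has("-R-I", "interference_training"))
  # interference logs use card set 2
  iset <- sim$logs$set_id[sim$logs$phase == "interference_training"]
  expect_true(all(iset == 2L))
})

test_that("mechanistic retest without decay keeps scores comparable", {
  effects <- dplyr::bind_rows(lapply(
    c("-R-I", "-R+I", "+R-I", "+R+I"),
    function(g) group_effect(g, mode = "mechanistic", decay = 1,
                             noise_sd = 0)))
  cfg <- cohort_config(n_total = 12, seed = 51, group_effects = effects,
                       protocol_phases = FALSE)
  sim <- simulate_cohort(cfg)
  scored <- score_cohort(sim$logs, combination_table(cfg$card_sets))
  wide <- scores_to_wide(scored$scores, sim$assignments)
  # resampling from unchanged weights: changes center near zero
  expect_lt(abs(mean(wide$test2 - wide$test1)), 10)
})

test_that("recovery report quantifies injection and exclusion fidelity", {
  cfg <- cohort_config(n_total = 24, seed = 61,
                       special = c(at_chance = 3, reversed = 2),
                       protocol_phases = FALSE)
  sim <- simulate_cohort(cfg)
  scored <- score_cohort(sim$logs, combination_table(cfg$card_sets))
  excl <- apply_exclusions(scored$scores, scored$compliance)
  wide <- scores_to_wide(scored$scores, sim$assignments) |>
    dplyr::filter(participant_id %in%
                    excl$participant_id[!excl$excluded])
  rec <- recovery_report(sim, wide, scored$scores, excl)
  expect_true(all(c("group", "estimated", "delta_mean", "bias") %in%
                    names(rec$groups)))
  expect_equal(rec$chance$tp + rec$chance$fn, 3)
  expect_equal(rec$reversals$tp + rec$reversals$fn, 2)
  expect_gte(rec$chance$tp, 2)  # injected at-chance scores sit inside the band
})
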