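test_that("adjusted score is the affine chance correction", {
  expect_equal(adjust_score(0.5), 0)
  expect_equal(adjust_score(1), 1)
  expect_equal(adjust_score(0.795), 0.59)
  expect_equal(adjust_score(0.6), 0.2)
  x <- seq(0, 1, 0.05)
  expect_true(all(diff(adjust_score(x)) > 0))
})

test_that("training compliance counts matches, non-responses as mismatches", {
  log <- tibble::tibble(
    phase = "training",
    displayed_outcome = rep(c("sun", "rain"), 100),
    response = rep(c("sun", "rain"), 100)
  )
  expect_equal(score_training_compliance(log), 1)
  log2 <- log
  log2$response[1:10] <- ifelse(log2$displayed_outcome[1:10] == "sun",
                                "rain", "sun")
  expect_equal(score_training_compliance(log2), 0.95)
  # exactly 8 non-responses: 192/200 = 0.96, the inclusive boundary
  log3 <- log
  log3$response[1:8] <- NA
  expect_equal(score_training_compliance(log3), 0.96)
  expect_false(score_training_compliance(log3) < 0.96)
  expect_error(score_training_compliance(log[0, ]), "empty")
})

test_that("chance band matches the exact binomial oracle", {
  for (n in c(50, 100, 137)) {
    band <- chance_range(n)
    inside <- band[["lo"]]:band[["hi"]]
    ps <- vapply(0:n, oracle_binom_p, numeric(1), n = n)
    expect_equal(which(ps > 0.05) - 1L, inside)
  }
  expect_equal(chance_range(100), c(lo = 40L, hi = 60L))
  expect_equal(chance_range(1), c(lo = 0L, hi = 1L))  # no power at n = 1
  expect_error(chance_range(100, alpha = 1.2), "alpha")
})

test_that("score_test counts optimal responses and handles non-responses", {
  log <- make_test_log(100, k_correct = 60)
  s <- score_test(log, default_combos)
  expect_equal(s$raw, 0.60)
  expect_equal(s$adjusted, 0.20)
  expect_true(s$at_chance)   # 60 sits on the band edge, still at chance
  # 10 unanswered, 60 correct among the answered: raw still 0.60
  log2 <- make_test_log(100, k_correct = 60, n_answered = 90)
  s2 <- score_test(log2, default_combos)
  expect_equal(s2$n_answered, 90)
  expect_equal(s2$raw, 0.60)
  expect_equal(s2$chance_p, oracle_binom_p(60, 100))
})

test_that("tie combinations drop out of numerator and denominator", {
  cards <- card_set(c(0.8, 0.6, 0.4, 0.2))  # cards 2+3 combine to 0.5
  combos <- enumerate_combinations(cards)
  expect_true(any(combos$optimal == "tie"))
  log <- withr::with_seed(4, {
    l <- generate_test_sequence(cards, 100)
    l$response <- ifelse(l$optimal == "tie", "sun", l$optimal)
    l
  })
  s <- score_test(log, combos)
  n_tie <- sum(log$optimal == "tie")
  expect_equal(s$n_trials, 100 - n_tie)
  expect_equal(s$raw, 1)
  expect_error(score_test(dplyr::mutate(log, combo = "9+9", optimal = NULL),
                          combos), "absent")
})

test_that("reversal detection flags and repairs only band-crossing flips", {
  log30 <- make_test_log(100, k_correct = 30)
  r <- repair_reversal(log30, default_combos)
  expect_true(r$score$reversed)
  expect_true(r$score$repaired)
  expect_equal(r$score$raw, 0.70)
  # repair is an involution on the log
  expect_identical(flip_responses(flip_responses(log30)), log30)
  expect_equal(sum(!is.na(r$log$response)), sum(!is.na(log30$response)))
  # inside the band: untouched
  log55 <- make_test_log(100, k_correct = 55)
  r55 <- repair_reversal(log55, default_combos)
  expect_false(r55$score$reversed)
  expect_identical(r55$log, log55)
  # low but not convincingly reversed (flip lands inside the band)
  log39 <- make_test_log(100, k_correct = 39, n_answered = 95)
  r39 <- repair_reversal(log39, default_combos)
  expect_false(r39$score$reversed)
})

test_that("cohort scoring fast path equals the log-level repair op", {
  withr::with_seed(9, {
    logs <- dplyr::bind_rows(lapply(1:8, function(i) {
      k <- sample(c(25, 35, 45, 55, 65, 75, 85), 1)
      na <- sample(90:100, 1)
      dplyr::mutate(
        make_test_log(100, min(k, na), na, seed = 100 + i,
                      phase = sample(c("test", "retest"), 1)),
        participant_id = sprintf("P%02d", i))
    }))
  })
  fast <- score_cohort(logs, default_combos)$scores
  slow <- logs |>
    dplyr::group_by(participant_id, phase) |>
    dplyr::group_map(function(d, key) {
      s <- repair_reversal(d, default_combos)$score
      dplyr::bind_cols(key, s)
    }) |>
    dplyr::bind_rows()
  merged <- dplyr::inner_join(
    fast, slow, by = c("participant_id", "phase"),
    suffix = c("_fast", "_slow"))
  expect_equal(nrow(merged), nrow(fast))
  expect_equal(merged$n_correct_fast, merged$n_correct_slow)
  expect_equal(merged$raw_fast, merged$raw_slow)
  expect_equal(merged$reversed_fast, merged$reversed_slow)
  expect_equal(merged$at_chance_fast, merged$at_chance_slow)
})

test_that("scoring commutes with global sun/rain relabeling", {
  # flip all card probabilities and all responses: scores must be identical
  cards <- card_set()
  cardsF <- card_set(1 - cards$p_sun)
  combosF <- enumerate_combinations(cardsF)
  log <- make_test_log(100, k_correct = 30, seed = 77)
  logF <- flip_responses(log)
  logF$optimal <- NULL   # force re-join against the flipped combination table
  a <- repair_reversal(log, default_combos)$score
  b <- repair_reversal(logF, combosF)$score
  expect_equal(a$n_correct, b$n_correct)
  expect_equal(a$reversed, b$reversed)
  expect_equal(a$raw, b$raw)
})

test_that("exclusion rules fire on compliance and chance, not on repair", {
  logs <- dplyr::bind_rows(
    # P1: compliant, above chance at both tests -> retained
    dplyr::mutate(make_test_log(100, 80, seed = 1), participant_id = "P1"),
    dplyr::mutate(make_test_log(100, 82, seed = 2, phase = "retest"),
                  participant_id = "P1"),
    # P2: at chance on initial test
    dplyr::mutate(make_test_log(100, 55, seed = 3), participant_id = "P2"),
    dplyr::mutate(make_test_log(100, 70, seed = 4, phase = "retest"),
                  participant_id = "P2"),
    # P3: reversed on retest, repairs to 0.70 -> retained
    dplyr::mutate(make_test_log(100, 75, seed = 5), participant_id = "P3"),
    dplyr::mutate(make_test_log(100, 30, seed = 6, phase = "retest"),
                  participant_id = "P3")
  )
  train <- function(id, m) {
    tibble::tibble(participant_id = id, phase = "training", set_id = 1L,
                   combo = "1", displayed_outcome = rep("sun", 200),
                   response = c(rep("sun", m), rep("rain", 200 - m)))
  }
  logs <- dplyr::bind_rows(
    logs,
    train("P1", 200), train("P2", 200), train("P3", 200),
    # P4: low training compliance (190/200), fine otherwise
    train("P4", 190),
    dplyr::mutate(make_test_log(100, 80, seed = 7), participant_id = "P4"),
    dplyr::mutate(make_test_log(100, 80, seed = 8, phase = "retest"),
                  participant_id = "P4")
  )
  scored <- score_cohort(logs, default_combos)
  excl <- apply_exclusions(scored$scores, scored$compliance)
  excl <- excl[order(excl$participant_id), ]
  expect_equal(excl$excluded, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(excl$reasons[[2]], "AT_CHANCE_TEST")
  expect_equal(excl$reasons[[4]], "LOW_TRAINING_COMPLIANCE")
  expect_equal(excl$repaired_sessions[[3]], "retest")
  smry <- exclusion_summary(excl, scored$scores)
  expect_equal(smry$n_excluded, 2)
  expect_equal(smry$n_repaired, 1)
})

test_that("pure guessers escape the chance flag at most 5% of the time", {
  # type-I error of the exclusion test, 10,000 simulated guessers
  withr::with_seed(123, {
    k <- rbinom(10000, 100, 0.5)
  })
  band <- chance_range(100)
  flagged_not_at_chance <- mean(k < band[["lo"]] | k > band[["hi"]])
  expect_lte(flagged_not_at_chance, 0.05)
})
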