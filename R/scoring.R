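#' Chance-corrected adjusted score
#'
#' Maps the raw fraction correct onto a scale where guessing is 0 and
#' perfection is 1: `adjusted = (raw - 0.5) / 0.5`.
#'
#' @param raw Raw fraction(s) correct in `[0, 1]`.
#' @return Adjusted score(s) in `[-1, 1]`.
#' @export
adjust_score <- function(raw) (raw - 0.5) / 0.5

#' Exact-binomial chance band
#'
#' The largest integer interval `[lo, hi]` of correct-response counts that
#' an exact two-sided binomial test (twice the smaller tail, capped at 1)
#' against p = 0.5 cannot distinguish from guessing at level `alpha`.  A
#' test score inside the band is "at chance" and triggers exclusion.  For
#' n = 100 at alpha = 0.05 the band is counts 40-60, i.e. raw scores
#' 40%-60%.
#'
#' @param n_trials Number of scoreable trials.
#' @param alpha Significance level of the chance test (default 0.05).
#' @return Named integer vector `c(lo = , hi = )`.
#' @export
#' @examples
#' chance_range(100)   # c(lo = 40, hi = 60)
chance_range <- function(n_trials, alpha = 0.05) {
  if (n_trials < 1) abort("`n_trials` must be at least 1.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie strictly in (0, 1).")
  x <- 0:n_trials
  keep <- which(binom_two_sided(x, n_trials) > alpha)
  c(lo = as.integer(min(keep) - 1L), hi = as.integer(max(keep) - 1L))
}

# exact two-sided binomial p against p = 0.5 (twice the smaller tail,
# capped at 1); vectorized over x.  P(X >= x) = P(X <= n - x) by symmetry.
binom_two_sided <- function(x, n) {
  pmin(1, 2 * pmin(pbinom(x, n, 0.5), pbinom(n - x, n, 0.5)))
}

#' Training compliance score
#'
#' The fraction of training trials on which the participant's response
#' matches the displayed weather outcome: an attention measure, since
#' training asks the participant to copy the shown outcome.  Non-responses
#' count as mismatches.  The study's exclusion rule drops participants
#' strictly below 0.96.
#'
#' @param training_log Trial tibble containing only training-phase rows
#'   (with a `displayed_outcome` and a `response` column; `NA` response =
#'   no key pressed).
#' @return A single fraction in `[0, 1]`.
#' @export
score_training_compliance <- function(training_log) {
  if (nrow(training_log) == 0) abort("empty training log.")
  if (any(is.na(training_log$displayed_outcome))) {
    abort("training log rows must all carry a displayed outcome.")
  }
  mean(!is.na(training_log$response) &
         training_log$response == training_log$displayed_outcome)
}

#' Score one test session
#'
#' A response is correct when it equals the optimal (highest-probability)
#' outcome of the displayed combination.  Non-responses are incorrect.
#' Trials whose combination has combined probability exactly 0.5 ("tie":
#' no optimal answer exists) are removed from both numerator and
#' denominator.  The chance band and two-sided binomial p are evaluated at
#' the effective trial count.
#'
#' @param test_log Trial tibble for a single test session, with `combo`
#'   and `response` columns.
#' @param combos Combination table ([enumerate_combinations()] or
#'   [combination_table()]) supplying the optimal outcome per combination.
#' @param alpha Chance-test significance level.
#' @return A one-row tibble: `n_trials` (effective), `n_answered`,
#'   `n_correct`, `raw`, `adjusted`, `chance_lo`, `chance_hi`, `chance_p`,
#'   `at_chance`, `reversed`, `repaired`.
#' @export
score_test <- function(test_log, combos, alpha = 0.05) {
  log <- test_log
  if (!"optimal" %in% names(log) || anyNA(log$optimal)) {
    key <- if ("set_id" %in% names(log) && "set_id" %in% names(combos)) {
      c("combo", "set_id")
    } else {
      "combo"
    }
    log$optimal <- NULL
    log <- dplyr::left_join(log, dplyr::distinct(combos[, c(key, "optimal")]),
                            by = key)
  }
  if (anyNA(log$optimal)) {
    abort("test log contains combinations absent from the combination table.")
  }
  log <- dplyr::filter(log, optimal != "tie")
  n <- nrow(log)
  if (n == 0) abort("no scoreable (non-tie) trials in test log.")
  n_answered <- sum(!is.na(log$response))
  n_correct <- sum(!is.na(log$response) & log$response == log$optimal)
  band <- chance_range(n, alpha)
  raw <- n_correct / n
  tibble(
    n_trials = n,
    n_answered = n_answered,
    n_correct = n_correct,
    raw = raw,
    adjusted = adjust_score(raw),
    chance_lo = band[["lo"]],
    chance_hi = band[["hi"]],
    chance_p = binom_two_sided(n_correct, n),
    at_chance = n_correct >= band[["lo"]] & n_correct <= band[["hi"]],
    reversed = FALSE,
    repaired = FALSE
  )
}

#' Flip the response keys of a session log
#'
#' Swaps `"sun"` and `"rain"` in the `response` column, leaving
#' non-responses (and non-weather responses such as reactivation card
#' counts) untouched.  Applying it twice restores the original log.
#'
#' @param log A trial tibble with a `response` column.
#' @return The log with flipped responses.
#' @export
flip_responses <- function(log) {
  log$response <- dplyr::case_when(
    log$response == "sun" ~ "rain",
    log$response == "rain" ~ "sun",
    TRUE ~ log$response
  )
  log
}

#' Detect and repair a spontaneous key reversal in one session
#'
#' A session shows strong evidence of whole-session key reversal when its
#' correct count is strictly below the chance band *and* the count after
#' flipping every answered response is strictly above it.  Flagged sessions
#' are repaired: responses flipped, session rescored, `reversed` and
#' `repaired` set.  Unflagged sessions are returned untouched.
#'
#' @inheritParams score_test
#' @return A list with elements `log` (possibly repaired) and `score`
#'   (one-row tibble as from [score_test()]).
#' @export
repair_reversal <- function(test_log, combos, alpha = 0.05) {
  s0 <- score_test(test_log, combos, alpha)
  flipped_correct <- s0$n_answered - s0$n_correct
  if (s0$n_correct < s0$chance_lo && flipped_correct > s0$chance_hi) {
    log <- flip_responses(test_log)
    s1 <- score_test(log, combos, alpha)
    s1$reversed <- TRUE
    s1$repaired <- TRUE
    list(log = log, score = s1)
  } else {
    list(log = test_log, score = s0)
  }
}

#' Score a whole cohort of session logs
#'
#' Scores every test-like session (`test`, `retest`, `interference_test`)
#' of every participant, applies the key-reversal repair pass, and computes
#' training compliance per participant.  Because tie trials are removed
#' before counting, flipping every answered response turns `n_correct` into
#' `n_answered - n_correct`, which is what the vectorized repair uses; the
#' log-level [repair_reversal()] gives identical results session by
#' session.
#'
#' @param logs Trial tibble for many participants/phases with columns
#'   `participant_id`, `phase`, `combo`, `set_id`, `response` (plus
#'   `displayed_outcome` on training rows).
#' @param combos Combination table covering every `set_id` in `logs`
#'   (default: both standard sets).
#' @param alpha Chance-test significance level.
#' @param repair Apply the reversal repair pass (default `TRUE`).
#' @return A list: `scores` (tibble, one row per participant x scored
#'   phase, columns as [score_test()]), `compliance` (tibble
#'   `participant_id`, `compliance`).
#' @export
score_cohort <- function(logs, combos = combination_table(), alpha = 0.05,
                         repair = TRUE) {
  test_phases <- c("test", "retest", "interference_test")
  key <- c("combo", "set_id")
  opt <- dplyr::distinct(combos[, c(key, "optimal")])

  sc <- logs |>
    dplyr::filter(phase %in% test_phases) |>
    dplyr::select(-dplyr::any_of("optimal")) |>
    dplyr::left_join(opt, by = key)
  if (anyNA(sc$optimal)) {
    abort("logs contain combinations absent from the combination table.")
  }
  sc <- sc |>
    dplyr::filter(optimal != "tie") |>
    dplyr::group_by(participant_id, phase) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_answered = sum(!is.na(response)),
      n_correct = sum(!is.na(response) & response == optimal),
      .groups = "drop"
    )

  bands <- lapply(unique(sc$n_trials), chance_range, alpha = alpha)
  names(bands) <- as.character(unique(sc$n_trials))
  sc$chance_lo <- unname(vapply(as.character(sc$n_trials),
                                function(k) bands[[k]][["lo"]], integer(1)))
  sc$chance_hi <- unname(vapply(as.character(sc$n_trials),
                                function(k) bands[[k]][["hi"]], integer(1)))

  flipped <- sc$n_answered - sc$n_correct
  sc$reversed <- sc$n_correct < sc$chance_lo & flipped > sc$chance_hi
  if (repair) {
    sc$n_correct <- ifelse(sc$reversed, flipped, sc$n_correct)
    sc$repaired <- sc$reversed
  } else {
    sc$repaired <- FALSE
  }
  sc <- sc |>
    dplyr::mutate(
      raw = n_correct / n_trials,
      adjusted = adjust_score(raw),
      chance_p = binom_two_sided(n_correct, n_trials),
      at_chance = n_correct >= chance_lo & n_correct <= chance_hi
    ) |>
    dplyr::relocate(raw, adjusted, .after = n_correct)

  compliance <- logs |>
    dplyr::filter(phase == "training") |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(
      compliance = mean(!is.na(response) & response == displayed_outcome),
      .groups = "drop"
    )

  list(scores = sc, compliance = compliance)
}

#' Apply the study's exclusion rules
#'
#' Rule (i): training compliance strictly below the threshold (lapses in
#' attention).  Rule (ii): at chance, post-repair, at the initial test or
#' the retest.  Repair alone never causes exclusion; repaired participants
#' are retained when their repaired scores clear the band.
#'
#' @param scores `scores` tibble from [score_cohort()] (post-repair).
#' @param compliance `compliance` tibble from [score_cohort()].
#' @param compliance_threshold Retention requires compliance `>=` this
#'   value (default 0.96; the boundary itself is retained).
#' @return A tibble: `participant_id`, `compliance`, `excluded`, `reasons`
#'   (list-column of character codes among `LOW_TRAINING_COMPLIANCE`,
#'   `AT_CHANCE_TEST`, `AT_CHANCE_RETEST`), `repaired_sessions`
#'   (list-column of phase names).
#' @export
apply_exclusions <- function(scores, compliance,
                             compliance_threshold = 0.96) {
  per <- compliance |>
    dplyr::left_join(
      scores |>
        dplyr::filter(phase %in% c("test", "retest")) |>
        dplyr::group_by(participant_id) |>
        dplyr::summarise(
          chance_test = any(phase == "test" & at_chance),
          chance_retest = any(phase == "retest" & at_chance),
          repaired_sessions = list(phase[repaired]),
          .groups = "drop"
        ),
      by = "participant_id"
    ) |>
    dplyr::mutate(
      chance_test = dplyr::coalesce(chance_test, FALSE),
      chance_retest = dplyr::coalesce(chance_retest, FALSE)
    )
  per$reasons <- purrr::pmap(
    list(per$compliance < compliance_threshold, per$chance_test,
         per$chance_retest),
    function(low, ct, cr) {
      c(if (low) "LOW_TRAINING_COMPLIANCE",
        if (ct) "AT_CHANCE_TEST",
        if (cr) "AT_CHANCE_RETEST")
    }
  )
  per$repaired_sessions <- purrr::map(per$repaired_sessions,
                                      function(x) x %||% character(0))
  per$excluded <- lengths(per$reasons) > 0
  per |>
    dplyr::select(participant_id, compliance, excluded, reasons,
                  repaired_sessions)
}
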