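#' Parameters of the synthetic task learner
#'
#' The generator's stand-in participant is an error-correcting associative
#' learner: it keeps one weight per card, updates them on every training
#' trial by `w <- w + learning_rate * (outcome - plogis(sum(w[shown])))`
#' for the shown cards (a delta/Rescorla-Wagner rule with a logistic
#' response), and at test chooses "sun" with probability
#' `plogis(sum(w[shown]) / temperature)`.  This is the simplest mechanism
#' that yields above-chance, sub-ceiling performance comparable to the
#' study cohort's roughly 80-point adjusted baseline.
#'
#' @param learning_rate Per-trial weight step in (0, 1].
#' @param temperature Response-noise scale (> 0); smaller is more
#'   deterministic.  The defaults put clean simulated cohorts at a mean
#'   baseline near 76-78 adjusted points (between-participant SD ~ 14),
#'   the ceiling this simple learner reaches on the default card
#'   probabilities; see the package vignette for the calibration.
#' @param temperature_sd SD of the per-participant log-normal temperature
#'   multiplier (between-participant skill heterogeneity).
#' @param lapse_prob Per-test-trial probability of a non-response.
#' @param compliance Probability a training trial's response copies the
#'   displayed outcome (else non-response); the attention measure.
#' @param reversal_prob Per-session probability that a participant
#'   spontaneously swaps the response keys for the whole session.
#' @return A list of class `learner_params`.
#' @export
learner_params <- function(learning_rate = 0.05, temperature = 0.05,
                           temperature_sd = 0.40, lapse_prob = 0.01,
                           compliance = 0.99, reversal_prob = 0) {
  stopifnot(
    learning_rate > 0, learning_rate <= 1,
    temperature > 0, temperature_sd >= 0,
    lapse_prob >= 0, lapse_prob < 1,
    compliance > 0, compliance <= 1,
    reversal_prob >= 0, reversal_prob <= 1
  )
  structure(
    list(learning_rate = learning_rate, temperature = temperature,
         temperature_sd = temperature_sd, lapse_prob = lapse_prob,
         compliance = compliance, reversal_prob = reversal_prob),
    class = "learner_params"
  )
}

#' Per-group retest effect specification
#'
#' @param group Group label.
#' @param delta_mean Target mean test-to-retest change, in adjusted-score
#'   points (0-100 scale).
#' @param delta_sd Between-participant SD of the injected change (>= 0).
#' @param mode `"direct"` (draw each participant's change and realize it
#'   exactly, to trial resolution, on the retest log) or `"mechanistic"`
#'   (decay/perturb the learner's weights before a fresh retest response
#'   pass).
#' @param decay,noise_sd Mechanistic-mode parameters: multiplicative
#'   weight decay in `[0, 1]` and SD of additive weight noise.
#' @return A one-row tibble.
#' @export
group_effect <- function(group, delta_mean = 0, delta_sd = 0,
                         mode = c("direct", "mechanistic"),
                         decay = 1, noise_sd = 0) {
  mode <- match.arg(mode)
  if (delta_sd < 0) abort("`delta_sd` must be >= 0.")
  tibble(group = group, delta_mean = delta_mean, delta_sd = delta_sd,
         mode = mode, decay = decay, noise_sd = noise_sd)
}

#' Default per-group effects patterned on the study's observed changes
#'
#' Means and SDs of absolute adjusted-score change per condition, used as
#' the generator's calibration targets.
#'
#' @return A four-row effects tibble.
#' @export
default_group_effects <- function() {
  dplyr::bind_rows(
    group_effect("-R-I", 1.39, 5.01),
    group_effect("-R+I", -0.64, 11.3),
    group_effect("+R-I", -0.94, 6.93),
    group_effect("+R+I", -6.02, 12.1)
  )
}

#' Configuration of a synthetic cohort
#'
#' @param n_total Number of simulated participants (default 69, the
#'   analyzed cohort size).
#' @param groups Group labels.
#' @param group_effects Effects tibble (see [group_effect()]); one row per
#'   group.
#' @param learner A [learner_params()] object.
#' @param card_sets Named list of stimulus sets (`"1"` for initial
#'   training, `"2"` for interference).
#' @param n_training,n_blocks,n_test Protocol trial counts (200 / 4 / 100).
#' @param alpha Chance-test level.
#' @param seed Master seed; the whole cohort is a pure function of it.
#' @param special Named integer vector of injected special participant
#'   types: `low_compliance` (training score below threshold),
#'   `at_chance` (test and retest scores drawn inside the chance band),
#'   `reversed` (one testing session recorded with flipped keys).
#' @param protocol_phases Also emit reactivation logs for +R groups and
#'   interference training/test logs for +I groups (protocol completeness;
#'   they do not enter the change analysis).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_total = 69,
                          groups = c("-R-I", "-R+I", "+R-I", "+R+I"),
                          group_effects = default_group_effects(),
                          learner = learner_params(),
                          card_sets = default_card_sets(),
                          n_training = 200L, n_blocks = 4L, n_test = 100L,
                          alpha = 0.05, seed = 1L,
                          special = c(low_compliance = 0L, at_chance = 0L,
                                      reversed = 0L),
                          protocol_phases = TRUE) {
  if (!all(groups %in% group_effects$group)) {
    abort("`group_effects` must cover every group label.")
  }
  spec <- c(low_compliance = 0L, at_chance = 0L, reversed = 0L)
  spec[names(special)] <- as.integer(special)
  if (sum(spec) > n_total) abort("more special participants than `n_total`.")
  structure(
    list(n_total = as.integer(n_total), groups = groups,
         group_effects = group_effects, learner = learner,
         card_sets = card_sets, n_training = as.integer(n_training),
         n_blocks = as.integer(n_blocks), n_test = as.integer(n_test),
         alpha = alpha, seed = as.integer(seed), special = spec,
         protocol_phases = protocol_phases),
    class = "cohort_config"
  )
}

# ---- internal simulation engines ------------------------------------------

# delta-rule weight learning over a training sequence; returns the weight
# vector (one per card id)
rw_train <- function(train_seq, combos, learning_rate, n_cards = 4L) {
  idx <- match(train_seq$combo, combos$combo)
  ids_list <- combos$card_ids[idx]
  y <- as.integer(train_seq$displayed_outcome == "sun")
  w <- numeric(n_cards)
  for (t in seq_along(ids_list)) {
    ids <- ids_list[[t]]
    p <- plogis(sum(w[ids]))
    w[ids] <- w[ids] + learning_rate * (y[t] - p)
  }
  w
}

# logistic choice responses for a test-like sequence, given weights
respond_from_weights <- function(seq_tbl, combos, w, temperature,
                                 lapse_prob) {
  idx <- match(seq_tbl$combo, combos$combo)
  strength <- vapply(combos$card_ids[idx],
                     function(ids) sum(w[ids]), numeric(1))
  p <- plogis(strength / temperature)
  resp <- ifelse(runif(nrow(seq_tbl)) < p, "sun", "rain")
  if (lapse_prob > 0) resp[runif(nrow(seq_tbl)) < lapse_prob] <- NA
  resp
}

# responses realizing an exact correctness pattern: k_correct optimal
# responses among n_answered answered non-tie trials
construct_scored_responses <- function(seq_tbl, k_correct, n_answered) {
  n <- nrow(seq_tbl)
  nontie <- which(seq_tbl$optimal != "tie")
  stopifnot(n_answered <= length(nontie), k_correct <= n_answered)
  ord <- sample(nontie)
  answered <- ord[seq_len(n_answered)]
  correct <- answered[seq_len(k_correct)]
  resp <- rep(NA_character_, n)
  opp <- ifelse(seq_tbl$optimal == "sun", "rain", "sun")
  resp[answered] <- opp[answered]
  resp[correct] <- seq_tbl$optimal[correct]
  tie <- setdiff(seq_len(n), nontie)
  if (length(tie)) resp[tie] <- sample(c("sun", "rain"), length(tie),
                                       replace = TRUE)
  resp
}

# correctness counts of a response vector against a sequence (non-tie only)
count_correct <- function(seq_tbl, resp) {
  keep <- seq_tbl$optimal != "tie"
  c(n_eff = sum(keep),
    n_answered = sum(keep & !is.na(resp)),
    n_correct = sum(keep & !is.na(resp) & resp == seq_tbl$optimal))
}

# nearest-achievable retest correct count for a target change in adjusted
# points, given a baseline count; vectorized (the DIRECT-mode core)
realize_change_counts <- function(k1, n_eff, n_answered, target_pts) {
  k2 <- k1 + round(n_eff * target_pts / 200)
  truncated <- k2 < 0 | k2 > n_answered
  k2 <- pmin(pmax(k2, 0), n_answered)
  list(k2 = k2, realized = 200 * (k2 - k1) / n_eff, truncated = truncated)
}

# ---- public per-participant operations ------------------------------------

#' Simulate one participant's training and initial test
#'
#' Runs the associative learner through a freshly generated training
#' sequence (responses copy the displayed outcome with probability
#' `compliance`, else non-response) and an initial test (logistic choice
#' from the learned weights, with lapses).
#'
#' @param params A [learner_params()].
#' @param cards Stimulus set for training/test.
#' @param n_training,n_blocks,n_test Protocol sizes.
#' @param seed Optional seed (one participant is a pure function of it).
#' @return A trial tibble of `training` and `test` rows with a `response`
#'   column; the learned weight vector and drawn temperature are attached
#'   as attributes `"weights"` and `"temperature"`.
#' @export
simulate_participant <- function(params, cards = card_set(),
                                 n_training = 200L, n_blocks = 4L,
                                 n_test = 100L, seed = NULL) {
  combos <- enumerate_combinations(cards)
  with_seed_or_ambient(seed, {
    temp <- params$temperature * exp(rnorm(1, 0, params$temperature_sd))
    train <- generate_training_sequence(cards, n_training, n_blocks)
    train$response <- ifelse(runif(n_training) < params$compliance,
                             train$displayed_outcome, NA_character_)
    w <- rw_train(train, combos, params$learning_rate, nrow(cards))
    test <- generate_test_sequence(cards, n_test)
    test$response <- respond_from_weights(test, combos, w, temp,
                                          params$lapse_prob)
    log <- dplyr::bind_rows(train, test)
    attr(log, "weights") <- w
    attr(log, "temperature") <- temp
    log
  })
}

#' Inject a controlled retest change (DIRECT mode)
#'
#' Draws a per-participant target change from
#' `Normal(delta_mean, delta_sd)` (adjusted points) and constructs a fresh
#' retest log whose score differs from the initial test by the nearest
#' achievable value at trial resolution (2 adjusted points per flipped
#' response).  Targets that would push the raw score outside what the
#' answered trials can express are truncated and flagged.
#'
#' @param test_log The participant's initial-test trial tibble.
#' @param cards Stimulus set used to build the retest sequence.
#' @param delta_mean,delta_sd Target change distribution, adjusted points.
#' @param seed Optional seed.
#' @param phase Phase label of the new log (default `"retest"`).
#' @return A list: `log` (retest trial tibble), `target`, `realized`
#'   (both adjusted points), `truncated`.
#' @export
inject_retest_effect <- function(test_log, cards = card_set(),
                                 delta_mean = 0, delta_sd = 0, seed = NULL,
                                 phase = "retest") {
  cnt <- count_correct(test_log, test_log$response)
  with_seed_or_ambient(seed, {
    target <- rnorm(1, delta_mean, delta_sd)
    retest <- generate_test_sequence(cards, nrow(test_log), phase = phase)
    n_eff <- sum(retest$optimal != "tie")
    # re-express the baseline on the retest's effective denominator
    k1 <- round(cnt[["n_correct"]] / cnt[["n_eff"]] * n_eff)
    n_ans <- min(round(cnt[["n_answered"]] / cnt[["n_eff"]] * n_eff), n_eff)
    r <- realize_change_counts(k1, n_eff, n_ans, target)
    retest$response <- construct_scored_responses(retest, r$k2, n_ans)
    list(log = retest, target = target,
         realized = r$realized, truncated = r$truncated)
  })
}

# mechanistic retest: decay/perturb weights, then a fresh response pass
mechanistic_retest <- function(test_log_template, cards, combos, w,
                               temperature, lapse_prob, decay = 1,
                               noise_sd = 0, phase = "retest") {
  w2 <- w * decay + rnorm(length(w), 0, noise_sd)
  retest <- generate_test_sequence(cards, nrow(test_log_template),
                                   phase = phase)
  retest$response <- respond_from_weights(retest, combos, w2, temperature,
                                          lapse_prob)
  retest
}

# ---- cohort-level simulation ----------------------------------------------

#' Simulate a full study cohort
#'
#' Simulates participants in arrival order (train, then initial test),
#' feeds each baseline adjusted score to the prospective randomizer,
#' applies the assigned group's retest effect, optionally emits the
#' protocol-completeness phases (reactivation for +R, interference
#' training/test for +I), and returns the trial logs together with a
#' ground-truth table of everything that was injected.  The entire cohort
#' is a pure function of `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list: `logs` (one trial tibble for the whole cohort),
#'   `assignments` (per-participant allocation decisions), `truth`
#'   (per-participant injected type, group, target and realized change,
#'   reversal flags), `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_total
  params <- config$learner
  cards1 <- config$card_sets[["1"]]
  cards2 <- config$card_sets[["2"]]
  combos1 <- enumerate_combinations(cards1)
  seed <- config$seed

  types <- rep("normal", n)
  if (sum(config$special) > 0) {
    types <- withr::with_seed(child_seed(seed, 1L), {
      pos <- sample(n, sum(config$special))
      types[pos] <- rep(names(config$special), config$special)
      types
    })
  }
  band <- chance_range(config$n_test, config$alpha)

  state <- allocation_state(config$groups, seed = child_seed(seed, 2L))
  part_logs <- vector("list", n)
  weights <- vector("list", n)
  temps <- numeric(n)
  test_true <- vector("list", n)   # unreversed test logs
  rev_test <- logical(n)
  decisions <- vector("list", n)
  ids <- sprintf("P%03d", seq_len(n))

  ## phase 1: arrival, training, initial test, streaming allocation
  for (i in seq_len(n)) {
    withr::with_seed(child_seed(seed, 100L + i), {
      temp <- params$temperature * exp(rnorm(1, 0, params$temperature_sd))
      train <- generate_training_sequence(cards1, config$n_training,
                                          config$n_blocks)
      if (types[i] == "low_compliance") {
        n_match <- sample(seq(round(0.86 * config$n_training),
                              ceiling(0.96 * config$n_training) - 1L), 1)
        match_idx <- sample(config$n_training, n_match)
        train$response <- NA_character_
        train$response[match_idx] <- train$displayed_outcome[match_idx]
      } else {
        train$response <- ifelse(runif(config$n_training) < params$compliance,
                                 train$displayed_outcome, NA_character_)
      }
      w <- rw_train(train, combos1, params$learning_rate, nrow(cards1))
      test <- generate_test_sequence(cards1, config$n_test)
      if (types[i] == "at_chance") {
        k <- sample(seq(band[["lo"]], band[["hi"]]), 1)
        test$response <- construct_scored_responses(
          test, k, sum(test$optimal != "tie"))
      } else {
        test$response <- respond_from_weights(test, combos1, w, temp,
                                              params$lapse_prob)
      }
      rev_test[i] <- (types[i] == "reversed" && runif(1) < 0.5) ||
        (types[i] == "normal" && runif(1) < params$reversal_prob)
      test_true[[i]] <- test
      recorded_test <- if (rev_test[i]) flip_responses(test) else test
      part_logs[[i]] <- list(train = train, test = recorded_test)
      weights[[i]] <- w
      temps[i] <- temp
    })
    # the allocator sees the recorded (possibly reversed) score, as the
    # live study would have
    cnt <- count_correct(part_logs[[i]]$test, part_logs[[i]]$test$response)
    baseline <- adjust_score(cnt[["n_correct"]] / cnt[["n_eff"]])
    step <- allocate(state, baseline, ids[i])
    state <- step$state
    decisions[[i]] <- step$decision
  }
  assignments <- dplyr::bind_rows(decisions)
  groups_of <- assignments$group

  ## phase 2: interval tasks and retest, by assigned group
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups_of[i]
    eff <- config$group_effects[config$group_effects$group == g, ]
    withr::with_seed(child_seed(seed, 200000L + i), {
      extra <- list()
      if (config$protocol_phases && grepl("\\+R", g)) {
        react <- generate_reactivation_sequence(cards1)
        react$response <- as.character(react$expected_response)
        extra$reactivation <- react
      }
      if (config$protocol_phases && grepl("\\+I", g)) {
        itrain <- generate_training_sequence(
          cards2, config$n_training, config$n_blocks,
          phase = "interference_training")
        itrain$response <- ifelse(runif(config$n_training) < params$compliance,
                                  itrain$displayed_outcome, NA_character_)
        combos2 <- enumerate_combinations(cards2)
        w2 <- rw_train(itrain, combos2, params$learning_rate, nrow(cards2))
        itest <- generate_test_sequence(cards2, config$n_test,
                                        phase = "interference_test")
        itest$response <- respond_from_weights(itest, combos2, w2, temps[i],
                                               params$lapse_prob)
        extra$itrain <- itrain
        extra$itest <- itest
      }

      if (types[i] == "at_chance") {
        retest <- generate_test_sequence(cards1, config$n_test,
                                         phase = "retest")
        k <- sample(seq(band[["lo"]], band[["hi"]]), 1)
        retest$response <- construct_scored_responses(
          retest, k, sum(retest$optimal != "tie"))
        inj <- list(log = retest, target = NA_real_, realized = NA_real_,
                    truncated = FALSE)
      } else if (eff$mode == "mechanistic") {
        retest <- mechanistic_retest(test_true[[i]], cards1, combos1,
                                     weights[[i]], temps[i],
                                     params$lapse_prob, eff$decay,
                                     eff$noise_sd)
        inj <- list(log = retest, target = NA_real_, realized = NA_real_,
                    truncated = FALSE)
      } else {
        inj <- inject_retest_effect(test_true[[i]], cards1,
                                    eff$delta_mean, eff$delta_sd)
      }
      rev_retest <- (types[i] == "reversed" && !rev_test[i]) ||
        (types[i] == "normal" && runif(1) < params$reversal_prob)
      recorded_retest <- if (rev_retest) flip_responses(inj$log) else inj$log

      pieces <- c(part_logs[[i]][c("train", "test")], extra,
                  list(retest = recorded_retest))
      combined <- dplyr::bind_rows(pieces)
      combined$participant_id <- ids[i]
      part_logs[[i]] <- combined[, c("participant_id",
                                     setdiff(names(combined),
                                             "participant_id"))]
      truth[[i]] <- fast_tibble(list(
        participant_id = ids[i], arrival = i, type = types[i], group = g,
        temperature = temps[i],
        baseline_adjusted = assignments$score[i] * 100,
        target_change = inj$target, realized_change = inj$realized,
        truncated = inj$truncated,
        reversed_test = rev_test[i], reversed_retest = rev_retest
      ))
    })
  }

  list(
    logs = dplyr::bind_rows(part_logs),
    assignments = assignments,
    truth = dplyr::bind_rows(truth),
    config = config
  )
}

#' Recovery metrics: what the pipeline estimated vs what was injected
#'
#' @param sim Output of [simulate_cohort()].
#' @param scores_wide Per-participant analysis table (from
#'   [scores_to_wide()]): `participant_id`, `group`, `test1`, `test2`.
#' @param session_scores `scores` tibble from [score_cohort()] (for
#'   repair flags).
#' @param exclusions Output of [apply_exclusions()].
#' @return A list: `groups` (per-group injected vs estimated mean change,
#'   bias, and RMSE of per-participant realized change about its target),
#'   `reversals` (confusion counts of injected vs repaired sessions),
#'   `chance` (confusion counts of injected at-chance participants vs
#'   at-chance exclusions).
#' @export
recovery_report <- function(sim, scores_wide, session_scores, exclusions) {
  est <- scores_wide |>
    dplyr::mutate(change = test2 - test1) |>
    dplyr::group_by(group) |>
    dplyr::summarise(estimated = mean(change), n = dplyr::n(),
                     .groups = "drop")
  inj <- sim$config$group_effects[, c("group", "delta_mean")]
  per <- sim$truth |>
    dplyr::filter(type == "normal", !is.na(target_change)) |>
    dplyr::group_by(group) |>
    dplyr::summarise(
      rmse_realization = sqrt(mean((realized_change - target_change)^2)),
      .groups = "drop"
    )
  groups <- est |>
    dplyr::left_join(inj, by = "group") |>
    dplyr::mutate(bias = estimated - delta_mean) |>
    dplyr::left_join(per, by = "group")

  repaired_ids <- session_scores |>
    dplyr::filter(repaired) |>
    dplyr::distinct(participant_id) |>
    dplyr::pull(participant_id)
  injected_rev <- sim$truth$participant_id[
    sim$truth$reversed_test | sim$truth$reversed_retest]
  all_ids <- sim$truth$participant_id
  reversals <- tibble(
    tp = sum(injected_rev %in% repaired_ids),
    fn = sum(!(injected_rev %in% repaired_ids)),
    fp = sum(!(repaired_ids %in% injected_rev)),
    tn = sum(!(all_ids %in% injected_rev) & !(all_ids %in% repaired_ids))
  )

  chance_excluded <- exclusions$participant_id[
    vapply(exclusions$reasons,
           function(r) any(grepl("^AT_CHANCE", r)), logical(1))]
  injected_chance <- sim$truth$participant_id[sim$truth$type == "at_chance"]
  chance <- tibble(
    tp = sum(injected_chance %in% chance_excluded),
    fn = sum(!(injected_chance %in% chance_excluded)),
    fp = sum(!(chance_excluded %in% injected_chance)),
    tn = sum(!(all_ids %in% injected_chance) &
               !(all_ids %in% chance_excluded))
  )

  list(groups = groups, reversals = reversals, chance = chance)
}
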