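#' Generate a balanced training sequence
#'
#' Training presents every card combination with near-equal frequency within
#' each block.  With the standard 200 trials in four 50-trial blocks and 14
#' combinations, each block holds every combination 3 times (42 trials); the
#' 8 leftover slots per block are assigned by a seeded rotation through the
#' canonical combination order, which keeps whole-session totals in
#' \{14, 15\}.  The displayed weather outcome of each trial is sampled from
#' the combination's combined probability.
#'
#' @param cards A [card_set()] tibble.
#' @param n_trials Total training trials (default 200).
#' @param n_blocks Number of blocks (default 4); must divide `n_trials`,
#'   and each block must be able to hold every combination at least once.
#' @param seed Optional seed; a fixed seed gives an identical sequence.
#' @param phase Phase label for the emitted rows.
#' @return A tibble of trial specifications: `phase`, `trial` (1-based),
#'   `block` (1-based), `combo`, `size`, `set_id`, `p_sun`, `optimal`,
#'   `displayed_outcome`.
#' @export
generate_training_sequence <- function(cards, n_trials = 200L, n_blocks = 4L,
                                       seed = NULL, phase = "training") {
  combos <- enumerate_combinations(cards)
  k <- nrow(combos)
  if (n_trials %% n_blocks != 0) {
    abort("`n_trials` must be divisible by `n_blocks`.")
  }
  m <- n_trials %/% n_blocks
  base <- m %/% k
  if (base < 1) {
    abort("each block must be long enough to show every combination at least once.")
  }
  leftover <- m - base * k

  with_seed_or_ambient(seed, {
    start <- if (leftover > 0) sample.int(k, 1) - 1L else 0L
    idx <- unlist(lapply(seq_len(n_blocks), function(b) {
      extra <- if (leftover > 0) {
        ((start + (b - 1L) * leftover + seq_len(leftover) - 1L) %% k) + 1L
      } else {
        integer(0)
      }
      sample(c(rep(seq_len(k), base), extra))
    }))
    p <- combos$p_sun[idx]
    fast_tibble(list(
      phase = rep(phase, n_trials),
      trial = seq_len(n_trials),
      block = rep(seq_len(n_blocks), each = m),
      combo = combos$combo[idx],
      size = combos$size[idx],
      set_id = rep(combos$set_id[1], n_trials),
      p_sun = p,
      optimal = combos$optimal[idx],
      displayed_outcome = sample_outcome(p)
    ))
  })
}

#' Generate a test (or retest) sequence
#'
#' A test shows the combinations with near-uniform frequency and no weather
#' symbol: with 100 trials and 14 combinations each appears 7 times and the
#' 2 remaining slots go to distinct combinations sampled without
#' replacement.  Order is shuffled.
#'
#' @inheritParams generate_training_sequence
#' @param n_trials Number of test trials (default 100; must be at least the
#'   number of combinations).
#' @param phase Phase label, e.g. `"test"`, `"retest"`,
#'   `"interference_test"`.
#' @return A trial tibble like [generate_training_sequence()]'s but with
#'   `block = NA` and `displayed_outcome = NA`.
#' @export
generate_test_sequence <- function(cards, n_trials = 100L, seed = NULL,
                                   phase = "test") {
  combos <- enumerate_combinations(cards)
  k <- nrow(combos)
  if (n_trials < k) {
    abort("a test must be able to show every combination at least once.")
  }
  base <- n_trials %/% k
  extra <- n_trials %% k

  with_seed_or_ambient(seed, {
    idx <- c(rep(seq_len(k), base),
             if (extra > 0) sample.int(k, extra) else integer(0))
    idx <- sample(idx)
    fast_tibble(list(
      phase = rep(phase, n_trials),
      trial = seq_len(n_trials),
      block = rep(NA_integer_, n_trials),
      combo = combos$combo[idx],
      size = combos$size[idx],
      set_id = rep(combos$set_id[1], n_trials),
      p_sun = combos$p_sun[idx],
      optimal = combos$optimal[idx],
      displayed_outcome = rep(NA_character_, n_trials)
    ))
  })
}

#' Generate a reactivation sequence
#'
#' Each of the 14 combinations is shown exactly once, in shuffled order,
#' without a weather symbol; the expected response is the number of cards
#' displayed (1-3), making this a shallow exposure task rather than a test.
#'
#' @inheritParams generate_training_sequence
#' @return A 14-row trial tibble with an `expected_response` column.
#' @export
generate_reactivation_sequence <- function(cards, seed = NULL,
                                           phase = "reactivation") {
  combos <- enumerate_combinations(cards)
  with_seed_or_ambient(seed, {
    idx <- sample(nrow(combos))
    k <- length(idx)
    fast_tibble(list(
      phase = rep(phase, k),
      trial = seq_along(idx),
      block = rep(NA_integer_, k),
      combo = combos$combo[idx],
      size = combos$size[idx],
      set_id = rep(combos$set_id[1], k),
      p_sun = combos$p_sun[idx],
      optimal = combos$optimal[idx],
      displayed_outcome = rep(NA_character_, k),
      expected_response = combos$size[idx]
    ))
  })
}

#' Sample trial outcomes from combined probabilities
#'
#' @param p_sun Vector of combined sun probabilities, one per trial.
#' @param seed Optional seed.
#' @return Character vector of `"sun"`/`"rain"` draws, one per element.
#' @export
sample_outcome <- function(p_sun, seed = NULL) {
  with_seed_or_ambient(seed, {
    ifelse(runif(length(p_sun)) < p_sun, "sun", "rain")
  })
}
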