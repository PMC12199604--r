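# Independent oracles and small fixture builders used across the suite.

# brute-force subset enumeration (size 1..max_k) via binary masks
oracle_subsets <- function(n_cards, max_k = 3) {
  out <- list()
  for (m in seq_len(2^n_cards - 1)) {
    ids <- which(bitwAnd(m, 2^(seq_len(n_cards) - 1)) > 0)
    if (length(ids) <= max_k) out[[length(out) + 1]] <- ids
  }
  out
}

# combination probability by brute-force Bayes: enumerate joint outcomes of
# independent cues on a fine grid of simulated draws is unnecessary — with a
# uniform prior over sun/rain the exact posterior is a likelihood ratio, here
# accumulated term by term without logistic shortcuts
oracle_combine <- function(p) {
  like_sun <- prod(p)
  like_rain <- prod(1 - p)
  like_sun / (like_sun + like_rain)
}

# exact two-sided binomial p via binom.test
oracle_binom_p <- function(x, n) stats::binom.test(x, n, 0.5)$p.value

# brute-force one-way ANOVA from explicit sums of squares
oracle_anova_F <- function(values, groups) {
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ss_between <- sum(ns * (means - gm)^2)
  ss_within <- sum((values - means[as.character(groups)])^2)
  df_b <- length(means) - 1
  df_w <- length(values) - length(means)
  (ss_between / df_b) / (ss_within / df_w)
}

# a minimal single-session test log with a chosen response pattern
make_test_log <- function(n = 100, k_correct = 60, n_answered = n,
                          cards = card_set(), phase = "test", seed = 1) {
  withr::with_seed(seed, {
    log <- generate_test_sequence(cards, n, phase = phase)
    log$response <- wptsim:::construct_scored_responses(log, k_correct,
                                                        n_answered)
    log
  })
}

default_combos <- enumerate_combinations(card_set())
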