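#' Define a set of cue cards
#'
#' A WPT stimulus set is four cards, each carrying a fixed probability that
#' the trial outcome is "sun".  The default probabilities give the classic
#' strong/weak cue structure (one strong and one weak predictor on each
#' side of 0.5) and are tie-free under the odds-product combination rule:
#' no 1-3 card combination has a combined probability of exactly 0.5.
#'
#' @param p_sun Numeric vector of per-card sun probabilities, one per card.
#' @param set_id Integer label of the stimulus set (1 = initial training,
#'   2 = interference training).
#' @param labels Optional card labels; defaults to the four object
#'   categories used on the printed cards.
#' @return A tibble with columns `card_id`, `label`, `set_id`, `p_sun`.
#' @export
#' @examples
#' card_set()
#' card_set(c(0.75, 0.55, 0.40, 0.20), set_id = 2)
card_set <- function(p_sun = c(0.80, 0.60, 0.45, 0.25), set_id = 1L,
                     labels = NULL) {
  if (!is.numeric(p_sun) || length(p_sun) < 1) {
    abort("`p_sun` must be a non-empty numeric vector.")
  }
  if (any(p_sun < 0 | p_sun > 1)) {
    abort("card probabilities must lie in [0, 1].")
  }
  if (is.null(labels)) {
    labels <- if (length(p_sun) == 4) {
      c("animal", "vehicle", "light", "small device")
    } else {
      paste0("card", seq_along(p_sun))
    }
  }
  tibble(
    card_id = seq_along(p_sun),
    label = labels,
    set_id = as.integer(set_id),
    p_sun = as.numeric(p_sun)
  )
}

#' Default stimulus sets for the two training phases
#'
#' @return A named list of two [card_set()] tibbles (`"1"` and `"2"`).
#' @export
default_card_sets <- function() {
  list(
    `1` = card_set(c(0.80, 0.60, 0.45, 0.25), set_id = 1L),
    `2` = card_set(c(0.75, 0.55, 0.40, 0.20), set_id = 2L)
  )
}

#' Combined sun probability of a card combination
#'
#' Combines independent cues by the odds product (naive Bayes with a uniform
#' prior): `odds = prod(p_i / (1 - p_i))`, `p = odds / (1 + odds)`.  A card
#' with `p_sun` exactly 0 (or 1) is decisive and forces the result to 0
#' (or 1); a combination containing both a 0 and a 1 card is contradictory
#' evidence and is an error.
#'
#' @param p_sun Sun probabilities of the displayed cards (length 1-3 in the
#'   standard task; any positive length is accepted).
#' @return A single probability.
#' @export
#' @examples
#' combine_probability(0.8)              # single card: identity
#' combine_probability(c(0.6, 0.4))      # complementary odds cancel: 0.5
#' combine_probability(c(0.8, 0.6))      # 6/7
combine_probability <- function(p_sun) {
  if (length(p_sun) < 1 || any(is.na(p_sun))) {
    abort("`p_sun` must contain at least one non-missing probability.")
  }
  if (any(p_sun < 0 | p_sun > 1)) {
    abort("card probabilities must lie in [0, 1].")
  }
  has0 <- any(p_sun == 0)
  has1 <- any(p_sun == 1)
  if (has0 && has1) {
    abort("contradictory evidence: combination mixes a p = 0 and a p = 1 card.")
  }
  if (has0) return(0)
  if (has1) return(1)
  # log-odds sum is numerically stable for small/large probabilities
  plogis(sum(qlogis(p_sun)))
}

#' Optimal (highest-probability) outcome for a combined probability
#'
#' The "correct" response in test scoring.  A combined probability of
#' exactly 0.5 is a first-class `"tie"`: neither outcome is optimal, and
#' such trials are dropped from score denominators downstream.
#'
#' @param p Combined sun probability (vectorized).
#' @return Character vector in `c("sun", "rain", "tie")`.
#' @export
optimal_outcome <- function(p) {
  dplyr::case_when(p > 0.5 ~ "sun", p < 0.5 ~ "rain", TRUE ~ "tie")
}

# per-session memo of enumerated combination tables (read-only reuse)
.combo_cache <- new.env(parent = emptyenv())

#' Enumerate all 1-3 card combinations of a stimulus set
#'
#' For the standard 4-card set this yields the 14 combinations of the task
#' (4 singletons, 6 pairs, 4 triples), in a canonical deterministic order:
#' by size, then lexicographically by card ids.  The operation generalizes
#' to hypothetical sets of other sizes (subsets of size 1 to
#' `min(max_cards, n)`), which is convenient for small worked examples.
#'
#' @param cards A [card_set()] tibble.
#' @param max_cards Largest subset size (3 in the standard task).
#' @return A tibble with one row per combination: `combo` (e.g. `"1+3"`),
#'   `size`, `card_ids` (list-column), `set_id`, `p_sun` (combined), and
#'   `optimal`.
#' @export
#' @examples
#' nrow(enumerate_combinations(card_set()))  # 14
enumerate_combinations <- function(cards, max_cards = 3L) {
  key <- paste(cards$set_id[1], paste(cards$p_sun, collapse = ","),
               max_cards, sep = "|")
  hit <- .combo_cache[[key]]
  if (!is.null(hit)) return(hit)
  ids <- sort(cards$card_id)
  sizes <- seq_len(min(max_cards, length(ids)))
  subsets <- unlist(
    lapply(sizes, function(k) combn(ids, k, simplify = FALSE)),
    recursive = FALSE
  )
  p <- vapply(
    subsets,
    function(s) combine_probability(cards$p_sun[match(s, cards$card_id)]),
    numeric(1)
  )
  out <- tibble(
    combo = vapply(subsets, paste, collapse = "+", FUN.VALUE = character(1)),
    size = lengths(subsets),
    card_ids = subsets,
    set_id = cards$set_id[1],
    p_sun = p,
    optimal = optimal_outcome(p)
  )
  .combo_cache[[key]] <- out
  out
}

#' Combination tables for several stimulus sets at once
#'
#' @param card_sets A list of [card_set()] tibbles (see
#'   [default_card_sets()]).
#' @return One tibble binding [enumerate_combinations()] of each set,
#'   distinguishable by `set_id`.
#' @export
combination_table <- function(card_sets = default_card_sets()) {
  dplyr::bind_rows(lapply(card_sets, enumerate_combinations))
}
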