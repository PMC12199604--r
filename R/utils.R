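#' Derive a reproducible child seed from a master seed
#'
#' All stochastic components of the package draw their randomness through
#' per-unit child seeds derived deterministically from a single master seed,
#' so that a whole study is a pure function of one integer.  The scheme is a
#' simple congruential mix kept below `.Machine$integer.max` so the result is
#' always a valid 32-bit seed.
#'
#' @param seed Master seed (single integer).
#' @param i Child index (single non-negative integer).
#' @return A single integer usable with [set.seed()].
#' @export
#' @examples
#' child_seed(1, 1:3)
child_seed <- function(seed, i) {
  as.integer(((seed %% 32768) * 32749 + i * 7919 + 104729) %% 2147483647)
}

# Evaluate `expr` under a temporary seed without touching the caller's RNG
# state; NULL seed means "use the ambient RNG stream".
with_seed_or_ambient <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

round_sig <- function(x, digits) signif(x, digits)

`%g%` <- function(x, fmt) formatC(x, format = "fg", digits = fmt)

# fast tibble construction for hot paths: skips tibble()'s quosure machinery
fast_tibble <- function(lst) {
  tibble::new_tibble(lst, nrow = length(lst[[1]]))
}
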