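#' Create a prospective-randomizer allocation state
#'
#' Running state of the streaming allocator that assigns each newly scored
#' participant to the experimental group that best equalizes baseline mean
#' scores without distorting group sizes.
#'
#' @param groups Character vector of group labels (default: the four
#'   reactivation x interference conditions).
#' @param size_slack Non-negative integer; a group is eligible for the next
#'   participant when its size is within `size_slack` of the smallest
#'   group.  The default 0 keeps sizes within 1 of each other at all times.
#' @param seed Seed used (only) for tie-breaking, so the allocation is a
#'   pure function of `(seed, arrival order, scores)`.
#' @return An object of class `allocation_state`.
#' @export
allocation_state <- function(groups = c("-R-I", "-R+I", "+R-I", "+R+I"),
                             size_slack = 0L, seed = NULL) {
  if (length(groups) < 2) abort("need at least two groups.")
  if (size_slack < 0) abort("`size_slack` must be >= 0.")
  structure(
    list(
      groups = groups,
      scores = stats::setNames(
        replicate(length(groups), numeric(0), simplify = FALSE), groups),
      size_slack = as.integer(size_slack),
      seed = seed,
      n_assigned = 0L
    ),
    class = "allocation_state"
  )
}

#' @export
print.allocation_state <- function(x, ...) {
  sizes <- lengths(x$scores)
  means <- vapply(x$scores,
                  function(s) if (length(s)) mean(s) else NA_real_,
                  numeric(1))
  cat("<allocation_state> ", x$n_assigned, " assigned\n", sep = "")
  print(tibble(group = x$groups, n = sizes, mean_baseline = means))
  invisible(x)
}

#' Assign one participant to a group
#'
#' Implements the minimization step: among the groups currently eligible by
#' size (the smallest ones, up to `size_slack`), each hypothetical
#' placement is scored by the spread of the resulting group means — the sum
#' of squared deviations of all non-empty group means from their grand
#' mean — and the participant joins the group with the smallest spread.
#' Exact ties are broken uniformly at random using a child seed derived
#' from the state's seed, so the stream stays reproducible.  Empty groups
#' are always minimal-size and therefore fill first.
#'
#' @param state An [allocation_state()].
#' @param score The participant's baseline (initial-test) score; any
#'   consistent scale works since only group means are compared.
#' @param participant_id Optional identifier carried into the decision.
#' @return A list with the updated `state` and a one-row `decision` tibble
#'   (`participant_id`, `score`, `group`, `objective`, `tie_broken`).
#' @export
allocate <- function(state, score, participant_id = NA) {
  sizes <- lengths(state$scores)
  eligible <- state$groups[sizes <= min(sizes) + state$size_slack]
  objective <- vapply(eligible, function(g) {
    tmp <- state$scores
    tmp[[g]] <- c(tmp[[g]], score)
    tmp <- tmp[lengths(tmp) > 0]
    means <- vapply(tmp, mean, numeric(1))
    sum((means - mean(means))^2)
  }, numeric(1))
  best <- objective <= min(objective) + 1e-12
  tie <- sum(best) > 1
  chosen <- if (tie) {
    s <- child_seed(state$seed %||% 0L, state$n_assigned + 1L)
    withr::with_seed(s, sample(eligible[best], 1))
  } else {
    eligible[which.min(objective)]
  }
  state$scores[[chosen]] <- c(state$scores[[chosen]], score)
  state$n_assigned <- state$n_assigned + 1L
  list(
    state = state,
    decision = fast_tibble(list(
      participant_id = participant_id,
      score = score,
      group = chosen,
      objective = min(objective),
      tie_broken = tie
    ))
  )
}

#' Allocate a whole arrival stream of baseline scores
#'
#' @param scores Numeric vector of baseline scores in arrival order.
#' @param participant_ids Optional identifiers (default `1:n`).
#' @inheritParams allocation_state
#' @return A tibble of decisions (one row per participant) with the final
#'   [allocation_state()] attached as attribute `"state"`.
#' @export
allocate_cohort <- function(scores, participant_ids = seq_along(scores),
                            groups = c("-R-I", "-R+I", "+R-I", "+R+I"),
                            size_slack = 0L, seed = NULL) {
  state <- allocation_state(groups, size_slack, seed)
  decisions <- vector("list", length(scores))
  for (i in seq_along(scores)) {
    step <- allocate(state, scores[i], participant_ids[i])
    state <- step$state
    decisions[[i]] <- step$decision
  }
  out <- dplyr::bind_rows(decisions)
  attr(out, "state") <- state
  out
}

#' Compare prospective allocation with uniform randomization
#'
#' Repeatedly allocates simulated baseline-score streams by (a) the
#' prospective minimization algorithm and (b) uniform randomization under
#' the same size-balance constraint, and reports the maximal pairwise gap
#' between group means under each.
#'
#' @param n_participants Cohort size per replicate.
#' @param reps Number of replicate cohorts.
#' @param rdist Function of `n` returning the baseline scores of one
#'   cohort; the default mimics adjusted initial-test scores near 0.81
#'   with SD 0.10.
#' @inheritParams allocation_state
#' @return A tibble with one row per replicate and method:
#'   `rep`, `method` (`"prospective"`/`"uniform"`), `max_gap`.
#' @export
simulate_balance <- function(n_participants, reps = 100,
                             rdist = function(n) rnorm(n, 0.81, 0.10),
                             groups = c("-R-I", "-R+I", "+R-I", "+R+I"),
                             size_slack = 0L, seed = NULL) {
  if (reps < 1) abort("`reps` must be >= 1.")
  one_rep <- function(r) {
    s <- child_seed(seed %||% 0L, r)
    withr::with_seed(s, {
      scores <- rdist(n_participants)
      uni <- sample(rep(groups, length.out = n_participants))
      list(scores = scores, uni = uni)
    }) -> draw
    pro <- allocate_cohort(draw$scores, groups = groups,
                           size_slack = size_slack,
                           seed = child_seed(s, 1L))$group
    tibble(
      rep = r,
      method = c("prospective", "uniform"),
      max_gap = c(max_group_gap(draw$scores, pro),
                  max_group_gap(draw$scores, draw$uni))
    )
  }
  dplyr::bind_rows(lapply(seq_len(reps), one_rep))
}

# largest absolute pairwise difference between group means
max_group_gap <- function(scores, group) {
  means <- tapply(scores, group, mean)
  means <- means[!is.na(means)]
  if (length(means) < 2) return(0)
  max(means) - min(means)
}

#' Checkpoint an allocation state to JSON
#'
#' Enables crash-safe resumption of a streaming allocation session.
#'
#' @param state An [allocation_state()].
#' @param path File to write.
#' @export
save_allocation_state <- function(state, path) {
  jsonlite::write_json(
    list(
      groups = state$groups,
      scores = state$scores,
      size_slack = state$size_slack,
      seed = state$seed,
      n_assigned = state$n_assigned
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Restore an allocation state from a JSON checkpoint
#'
#' @param path File written by [save_allocation_state()].
#' @return An [allocation_state()].
#' @export
load_allocation_state <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  state <- allocation_state(raw$groups, raw$size_slack,
                            if (is.null(raw$seed)) NULL else raw$seed)
  state$scores <- lapply(raw$scores, as.numeric)
  # empty groups deserialize as list(); normalize
  state$scores <- stats::setNames(
    lapply(state$scores, function(s) if (length(s)) s else numeric(0)),
    raw$groups
  )
  state$n_assigned <- as.integer(raw$n_assigned)
  state
}

#' Serve one line of the streaming allocation protocol
#'
#' The line protocol mirrors how experiment software can stream
#' enrollments to the allocator over a socket: one JSON object per request,
#' `{"participant_id": ..., "score": ...}`, answered by
#' `{"participant_id": ..., "group": ...}`.
#'
#' @param state An [allocation_state()].
#' @param line A single JSON request line.
#' @return A list with the updated `state` and the JSON `response` string.
#' @export
handle_allocation_request <- function(state, line) {
  req <- jsonlite::fromJSON(line)
  if (is.null(req$score)) abort("request line must carry a `score` field.")
  step <- allocate(state, as.numeric(req$score),
                   req$participant_id %||% NA)
  list(
    state = step$state,
    response = jsonlite::toJSON(
      list(participant_id = step$decision$participant_id,
           group = step$decision$group),
      auto_unbox = TRUE
    )
  )
}
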