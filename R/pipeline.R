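#' Pivot session scores into the per-participant analysis table
#'
#' @param scores `scores` tibble from [score_cohort()].
#' @param assignments Allocation decisions (tibble with `participant_id`
#'   and `group`).
#' @return A tibble with one row per participant: `participant_id`,
#'   `group`, `test1`, `test2` (adjusted scores on the 0-100 point scale).
#' @export
scores_to_wide <- function(scores, assignments) {
  scores |>
    dplyr::filter(phase %in% c("test", "retest")) |>
    dplyr::mutate(points = 100 * adjusted) |>
    dplyr::select(participant_id, phase, points) |>
    tidyr::pivot_wider(names_from = phase, values_from = points) |>
    dplyr::rename(test1 = test, test2 = retest) |>
    dplyr::left_join(assignments[, c("participant_id", "group")],
                     by = "participant_id") |>
    dplyr::relocate(group, .after = participant_id)
}

#' Read a study configuration from YAML or JSON
#'
#' Any field of [cohort_config()] may appear; omitted fields keep their
#' defaults.  Card sets are given as lists of sun probabilities, e.g.
#' `card_sets: {"1": [0.8, 0.6, 0.45, 0.25], "2": [...]}`; group effects
#' as a table with `group`, `delta_mean`, `delta_sd` (and optionally
#' `mode`, `decay`, `noise_sd`) columns.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A [cohort_config()].
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  for (f in c("n_total", "groups", "n_training", "n_blocks", "n_test",
              "alpha", "seed", "protocol_phases")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  if (!is.null(raw$card_sets)) {
    args$card_sets <- lapply(names(raw$card_sets), function(id) {
      card_set(as.numeric(raw$card_sets[[id]]), set_id = as.integer(id))
    })
    names(args$card_sets) <- names(raw$card_sets)
  }
  if (!is.null(raw$group_effects)) {
    ge <- as_tibble(lapply(raw$group_effects, unlist))
    args$group_effects <- dplyr::bind_rows(lapply(seq_len(nrow(ge)),
      function(i) do.call(group_effect, as.list(ge[i, ]))))
  }
  if (!is.null(raw$learner)) {
    args$learner <- do.call(learner_params, raw$learner)
  }
  if (!is.null(raw$special)) args$special <- unlist(raw$special)
  do.call(cohort_config, args)
}

#' Write and read session-log CSV
#'
#' UTF-8, comma-separated, header row; missing responses are empty fields.
#'
#' @param logs Trial tibble (as produced by [simulate_cohort()]).
#' @param path CSV file.
#' @export
write_session_logs <- function(logs, path) {
  readr::write_csv(logs, path, na = "")
  invisible(path)
}

#' @rdname write_session_logs
#' @export
read_session_logs <- function(path) {
  readr::read_csv(
    path, na = "",
    col_types = readr::cols(
      participant_id = readr::col_character(),
      phase = readr::col_character(),
      trial = readr::col_integer(),
      block = readr::col_integer(),
      combo = readr::col_character(),
      size = readr::col_integer(),
      set_id = readr::col_integer(),
      p_sun = readr::col_double(),
      optimal = readr::col_character(),
      displayed_outcome = readr::col_character(),
      response = readr::col_character(),
      .default = readr::col_character()
    )
  )
}

#' Run the whole study pipeline
#'
#' `simulate -> allocate -> score -> repair -> exclude -> analyze` as one
#' reproducible call: simulates the cohort (the allocator runs inside the
#' simulation, as in the live study), scores every session with the
#' reversal-repair pass, applies the exclusion rules, and builds the
#' per-group summary report from the retained participants.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, writes `logs.csv`,
#'   `scores.csv`, `analysis.csv`, `exclusions.json`, `truth.json`,
#'   `report.csv` and `manifest.json` there.
#' @return A list: `sim` (from [simulate_cohort()]), `scored` (from
#'   [score_cohort()]), `exclusions`, `analysis` (retained wide score
#'   table), `report` (a `wpt_report`), `manifest`.
#' @export
run_study <- function(config = cohort_config(), out_dir = NULL) {
  sim <- simulate_cohort(config)
  combos <- combination_table(config$card_sets)
  scored <- score_cohort(sim$logs, combos, alpha = config$alpha)
  exclusions <- apply_exclusions(scored$scores, scored$compliance)
  retained <- exclusions$participant_id[!exclusions$excluded]
  analysis <- scores_to_wide(scored$scores, sim$assignments) |>
    dplyr::filter(participant_id %in% retained)
  report <- build_summary_table(analysis, alpha = config$alpha)

  manifest <- list(
    package_version = as.character(utils::packageVersion("wptsim")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_total = config$n_total,
    n_retained = length(retained),
    n_excluded = sum(exclusions$excluded),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_session_logs(sim$logs, file.path(out_dir, "logs.csv"))
    readr::write_csv(scored$scores, file.path(out_dir, "scores.csv"))
    readr::write_csv(analysis, file.path(out_dir, "analysis.csv"))
    jsonlite::write_json(
      exclusions |>
        dplyr::mutate(
          reasons = purrr::map_chr(reasons, paste, collapse = ";"),
          repaired_sessions = purrr::map_chr(repaired_sessions, paste,
                                             collapse = ";")),
      file.path(out_dir, "exclusions.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    write_report_csv(report, file.path(out_dir, "report.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(sim = sim, scored = scored, exclusions = exclusions,
       analysis = analysis, report = report, manifest = manifest)
}

#' Summary counts of an exclusion report
#'
#' @param exclusions Output of [apply_exclusions()].
#' @param session_scores `scores` tibble from [score_cohort()].
#' @return A one-row tibble: `n`, `n_excluded`, `n_low_compliance`,
#'   `n_at_chance`, `n_repaired` (participants with at least one repaired
#'   session).
#' @export
exclusion_summary <- function(exclusions, session_scores) {
  has <- function(code) {
    vapply(exclusions$reasons, function(r) any(r == code), logical(1))
  }
  chance <- has("AT_CHANCE_TEST") | has("AT_CHANCE_RETEST")
  repaired_ids <- unique(session_scores$participant_id[
    session_scores$repaired])
  tibble(
    n = nrow(exclusions),
    n_excluded = sum(exclusions$excluded),
    n_low_compliance = sum(has("LOW_TRAINING_COMPLIANCE")),
    n_at_chance = sum(chance),
    n_repaired = length(repaired_ids)
  )
}
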