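#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a group summary report
#'
#' Mean test-retest change per group with standard-error bars, for the
#' absolute and (when available) percent modes.
#'
#' @param object A `wpt_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wpt_report <- function(object, ...) {
  g <- object$groups
  long <- dplyr::bind_rows(
    tibble(group = g$group, mode = "absolute",
           mean = g$change_abs_mean, sem = g$change_abs_sem),
    tibble(group = g$group, mode = "percent",
           mean = g$change_pct_mean, sem = g$change_pct_sem)
  ) |>
    dplyr::filter(!is.na(mean))
  ggplot2::ggplot(long, ggplot2::aes(x = group, y = mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mean - sem, ymax = mean + sem), width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~mode, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "test-retest change (adjusted points)") +
    ggplot2::theme_minimal()
}

#' Plot an allocation-balance comparison
#'
#' Distribution of the maximal pairwise baseline-mean gap under
#' prospective vs uniform allocation, from [simulate_balance()].
#'
#' @param balance Tibble returned by [simulate_balance()].
#' @return A ggplot object.
#' @export
plot_allocation_balance <- function(balance) {
  ggplot2::ggplot(balance,
                  ggplot2::aes(x = method, y = max_gap, fill = method)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "max pairwise gap in group baseline means") +
    ggplot2::theme_minimal()
}

#' Plot block-wise training progress of simulated participants
#'
#' Shows, per training block, the rate at which the displayed outcome
#' matched the optimal outcome of the shown combination (the ceiling a
#' perfect learner could track) alongside nothing participant-specific:
#' training responses copy the display, so learning is visible only at
#' test.  Included as a sequence diagnostic.
#'
#' @param logs Trial tibble containing training rows.
#' @return A ggplot object.
#' @export
plot_training_outcomes <- function(logs) {
  d <- logs |>
    dplyr::filter(phase == "training") |>
    dplyr::group_by(block) |>
    dplyr::summarise(outcome_optimal_rate =
                       mean(displayed_outcome == optimal),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(block, outcome_optimal_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training block",
                  y = "P(displayed outcome = optimal)") +
    ggplot2::theme_minimal()
}
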