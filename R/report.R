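#' Build the per-group performance summary table
#'
#' Produces the study-report layout: per group, initial test and retest
#' means (+/- sem), absolute and percent test-retest improvement with SD,
#' one-sample t, two-sided p and Cohen's d, plus the baseline one-way ANOVA
#' on initial-test scores and the change-score ANOVAs (absolute and
#' percent) with Fisher's LSD post hocs.  Groups with fewer than two
#' participants cannot support the inference and are dropped with a
#' warning.
#'
#' @param scores A tibble with one row per participant: `participant_id`,
#'   `group`, `test1`, `test2` (adjusted scores on the 0-100 point scale).
#' @param alpha Significance threshold used for post-hoc flags.
#' @return An object of class `wpt_report`: a list with `groups` (per-group
#'   summary tibble), `anova` (list `baseline`, `absolute`, `percent` of
#'   `wpt_anova` objects or `NULL` when fewer than two groups remain),
#'   `dropped` (labels of dropped groups) and `data` (the per-participant
#'   change tibble).  Has [print()], [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
build_summary_table <- function(scores, alpha = 0.05) {
  needed <- c("participant_id", "group", "test1", "test2")
  if (!all(needed %in% names(scores))) {
    abort(paste("`scores` must have columns:", paste(needed, collapse = ", ")))
  }
  counts <- table(scores$group)
  dropped <- names(counts)[counts < 2]
  if (length(dropped)) {
    warn(paste("dropping group(s) with fewer than 2 participants:",
               paste(dropped, collapse = ", ")))
    scores <- dplyr::filter(scores, !group %in% dropped)
  }
  if (nrow(scores) == 0) abort("no analyzable groups.")

  data <- scores |>
    dplyr::mutate(
      change_abs = paired_change(test1, test2, "absolute"),
      change_pct = paired_change(test1, test2, "percent")
    )

  one_group <- function(d) {
    abs_t <- one_sample_t(d$change_abs)
    pct <- d$change_pct[!is.na(d$change_pct)]
    pct_t <- if (length(pct) >= 2) one_sample_t(pct) else NULL
    tibble(
      group = d$group[1],
      n = nrow(d),
      test1_mean = mean(d$test1), test1_sem = sd(d$test1) / sqrt(nrow(d)),
      test2_mean = mean(d$test2), test2_sem = sd(d$test2) / sqrt(nrow(d)),
      change_abs_mean = abs_t$mean, change_abs_sem = abs_t$sem,
      sd_abs = abs_t$sd, t_abs = abs_t$t, p_abs = abs_t$p, d_abs = abs_t$d,
      change_pct_mean = if (is.null(pct_t)) NA_real_ else pct_t$mean,
      change_pct_sem = if (is.null(pct_t)) NA_real_ else pct_t$sem,
      sd_pct = if (is.null(pct_t)) NA_real_ else pct_t$sd,
      t_pct = if (is.null(pct_t)) NA_real_ else pct_t$t,
      p_pct = if (is.null(pct_t)) NA_real_ else pct_t$p,
      d_pct = if (is.null(pct_t)) NA_real_ else pct_t$d
    )
  }
  groups_tbl <- data |>
    dplyr::group_split(group) |>
    purrr::map(one_group) |>
    dplyr::bind_rows()

  k <- nrow(groups_tbl)
  anova <- if (k >= 2) {
    list(
      baseline = one_way_anova(data, test1, group),
      absolute = one_way_anova(data, change_abs, group),
      percent = if (sum(!is.na(data$change_pct)) >= 4)
        one_way_anova(dplyr::filter(data, !is.na(change_pct)),
                      change_pct, group) else NULL
    )
  } else {
    NULL
  }

  structure(
    list(groups = groups_tbl, anova = anova, dropped = dropped,
         data = data, alpha = alpha),
    class = "wpt_report"
  )
}

#' Analyze a printed summary table from its moments
#'
#' Verification mode for published per-group summaries: feed the printed
#' (mean, sem, n) of a change row and recover sd, t, two-sided p and
#' Cohen's d under the standard conventions.
#'
#' @param moments A tibble with columns `group`, `mean`, `sem`, `n`.
#' @return The [summary_from_moments()] tibble.
#' @export
analyze_from_moments <- function(moments) {
  needed <- c("group", "mean", "sem", "n")
  if (!all(needed %in% names(moments))) {
    abort(paste("`moments` must have columns:", paste(needed, collapse = ", ")))
  }
  summary_from_moments(moments$mean, moments$sem, moments$n, moments$group)
}

#' @export
print.wpt_report <- function(x, ...) {
  g <- x$groups
  fmt_ms <- function(m, s) sprintf("%.4g ± %.3g", m, s)
  rows <- rbind(
    N = sprintf("%d", g$n),
    `Initial test (Test 1)` = fmt_ms(g$test1_mean, g$test1_sem),
    `Retest (Test 2)` = fmt_ms(g$test2_mean, g$test2_sem),
    `Absolute improvement` = fmt_ms(g$change_abs_mean, g$change_abs_sem),
    `Percent improvement` = fmt_ms(g$change_pct_mean, g$change_pct_sem),
    `SD (absolute)` = sprintf("%.3g", g$sd_abs),
    `SD (percent)` = sprintf("%.3g", g$sd_pct),
    `p (abs.)` = sprintf("%.3f", g$p_abs),
    `p (%)` = sprintf("%.3f", g$p_pct),
    `t (abs.)` = sprintf("%.2g", g$t_abs),
    `t (%)` = sprintf("%.2g", g$t_pct),
    `d (abs.)` = sprintf("%.2g", g$d_abs),
    `d (%)` = sprintf("%.2g", g$d_pct)
  )
  colnames(rows) <- g$group
  cat("Performance by group (adjusted-score points)\n")
  print(rows, quote = FALSE)
  if (!is.null(x$anova)) {
    cat(sprintf("\nBaseline (Test 1) one-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
                x$anova$baseline$df_between, x$anova$baseline$df_within,
                x$anova$baseline$F, x$anova$baseline$p))
    cat(sprintf("Absolute change ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
                x$anova$absolute$df_between, x$anova$absolute$df_within,
                x$anova$absolute$F, x$anova$absolute$p))
    if (!is.null(x$anova$percent)) {
      cat(sprintf("Percent change ANOVA:  F(%d, %d) = %.3g, p = %.3g\n",
                  x$anova$percent$df_between, x$anova$percent$df_within,
                  x$anova$percent$F, x$anova$percent$p))
    }
    sig <- dplyr::filter(x$anova$absolute$posthoc, significant)
    if (nrow(sig)) {
      cat("LSD-significant pairs (absolute change):",
          paste(sprintf("%s vs %s (p = %.3f)", sig$group1, sig$group2, sig$p),
                collapse = "; "), "\n")
    }
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wpt_report <- function(x, ...) {
  tidyr::pivot_longer(x$groups, -c(group, n),
                      names_to = "metric", values_to = "value")
}

#' @exportS3Method generics::glance
glance.wpt_report <- function(x, ...) {
  if (is.null(x$anova)) {
    return(tibble(n_groups = nrow(x$groups), n = sum(x$groups$n)))
  }
  tibble(
    n_groups = nrow(x$groups), n = sum(x$groups$n),
    baseline_F = x$anova$baseline$F, baseline_p = x$anova$baseline$p,
    abs_F = x$anova$absolute$F, abs_p = x$anova$absolute$p,
    pct_F = if (is.null(x$anova$percent)) NA_real_ else x$anova$percent$F,
    pct_p = if (is.null(x$anova$percent)) NA_real_ else x$anova$percent$p
  )
}

#' Export a report's group table to CSV
#'
#' @param x A `wpt_report`.
#' @param path Output file.
#' @export
write_report_csv <- function(x, path) {
  readr::write_csv(x$groups, path)
  invisible(path)
}
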