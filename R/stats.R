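#' Per-participant test-retest change
#'
#' Change is computed on adjusted scores throughout.  `"absolute"` change
#' is `t2 - t1` (adjusted-score points); `"percent"` change is
#' `100 * (t2 - t1) / t1`, computed per participant and then averaged —
#' which is not the same as the ratio of group means.  Participants with a
#' baseline of exactly 0 cannot have a percent change; they come back `NA`
#' with a warning.
#'
#' @param test1,test2 Paired vectors of adjusted scores (any consistent
#'   scale; the study reports adjusted points on a 0-100 scale).
#' @param mode `"absolute"` or `"percent"`.
#' @return Numeric change vector, same length as the inputs.
#' @export
#' @examples
#' paired_change(81.8, 83.2)                       # +1.4
#' paired_change(80, 72, mode = "percent")         # -10
paired_change <- function(test1, test2, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  if (length(test1) != length(test2)) {
    abort("`test1` and `test2` must be paired (same length).")
  }
  if (mode == "absolute") {
    test2 - test1
  } else {
    if (any(test1 == 0, na.rm = TRUE)) {
      warn("baseline of 0: percent change undefined for some participants; returning NA.")
    }
    ifelse(test1 == 0, NA_real_, 100 * (test2 - test1) / test1)
  }
}

#' One-sample t test of a change vector against zero
#'
#' @param changes Numeric vector (missing values dropped), `n >= 2`.
#' @return A one-row tibble: `n`, `mean`, `sd`, `sem`, `t`, `df`, `p`,
#'   `d` (Cohen's d = mean/sd), `degenerate` (`TRUE` when the sample has
#'   zero variance, in which case `t` is 0 or signed infinity).
#' @export
#' @examples
#' one_sample_t(c(1, 2, 3))  # t = 3.46, df = 2
one_sample_t <- function(changes) {
  x <- changes[!is.na(changes)]
  n <- length(x)
  if (n < 2) abort("need at least two observations.")
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    return(tibble(n = n, mean = m, sd = 0, sem = 0, t = t, df = n - 1,
                  p = if (m == 0) 1 else 0, d = NA_real_,
                  degenerate = TRUE))
  }
  ht <- stats::t.test(x)
  tibble(
    n = n, mean = m, sd = s, sem = s / sqrt(n),
    t = unname(ht$statistic), df = n - 1, p = ht$p.value,
    d = m / s, degenerate = FALSE
  )
}

#' Change statistics from printed summary moments
#'
#' Reconstructs the full one-sample inference from (mean, sem, n) alone:
#' `sd = sem * sqrt(n)`, `t = mean / sem`, two-sided p on `n - 1` degrees
#' of freedom, `d = mean / sd`.  This is how the package verifies a printed
#' summary table without access to raw data.
#'
#' @param mean,sem,n Vectors of group means, standard errors, and sizes.
#' @param group Optional group labels.
#' @return A tibble with one row per group: `group`, `n`, `mean`, `sem`,
#'   `sd`, `t`, `df`, `p`, `d`.
#' @export
#' @examples
#' summary_from_moments(-6.02, 2.84, 18)  # t = -2.12, p = 0.049
summary_from_moments <- function(mean, sem, n, group = NULL) {
  if (any(n < 2)) abort("need n >= 2.")
  if (any(sem <= 0)) abort("`sem` must be positive.")
  s <- sem * sqrt(n)
  t <- mean / sem
  tibble(
    group = group %||% as.character(seq_along(mean)),
    n = n, mean = mean, sem = sem, sd = s,
    t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1), d = mean / s
  )
}

#' Cohen's d for one-sample change scores
#'
#' The standard one-sample convention `d = mean / sd`.
#'
#' @param changes Numeric vector, `n >= 2` with positive variance.
#' @return A single number.
#' @export
cohens_d <- function(changes) {
  x <- changes[!is.na(changes)]
  if (length(x) < 2) abort("need at least two observations.")
  s <- sd(x)
  if (s == 0) {
    warn("zero variance: Cohen's d undefined.")
    return(NA_real_)
  }
  mean(x) / s
}

#' Unpaired two-sample Student's t test
#'
#' Equal-variance (pooled) by default, matching the study's convention;
#' Welch available via `var_equal = FALSE`.
#'
#' @param a,b Numeric samples (each `n >= 2`).
#' @param var_equal Pool the variances (default `TRUE`).
#' @return A one-row tibble: `mean_a`, `mean_b`, `diff`, `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("each sample needs n >= 2.")
  ht <- stats::t.test(a, b, var.equal = var_equal)
  tibble(
    mean_a = mean(a), mean_b = mean(b), diff = mean(a) - mean(b),
    t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value
  )
}

#' One-way ANOVA with Fisher's LSD post hocs
#'
#' Classic between/within decomposition fitted with [stats::aov()],
#' followed by Fisher's LSD pairwise comparisons: pairwise t statistics on
#' the pooled within-group mean square and its degrees of freedom, with
#' unadjusted two-sided p values (the LSD convention; protected by the
#' omnibus test).  A fit with zero within-group variance but between-group
#' differences is flagged with `F = Inf`.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the response and the
#'   group factor.
#' @return An object of class `wpt_anova` with [tidy()] (pairwise rows)
#'   and [glance()] (omnibus row) methods.
#' @export
one_way_anova <- function(data, value, group) {
  df <- dplyr::transmute(data,
                         value = {{ value }},
                         group = factor({{ group }}))
  df <- dplyr::filter(df, !is.na(value))
  k <- nlevels(droplevels(df$group))
  if (k < 2) abort("need at least two groups.")
  if (any(table(df$group) < 2)) abort("each group needs n >= 2.")
  df$group <- droplevels(df$group)

  fit <- aov(value ~ group, data = df)
  ss <- summary(fit)[[1]]
  ss_between <- ss[["Sum Sq"]][1]
  ss_within <- ss[["Sum Sq"]][2]
  df_between <- ss[["Df"]][1]
  df_within <- ss[["Df"]][2]
  mse <- ss_within / df_within
  if (mse <= .Machine$double.eps * max(1, ss_between)) {
    f <- if (ss_between > 0) Inf else 0
    p <- if (ss_between > 0) 0 else 1
  } else {
    f <- (ss_between / df_between) / mse
    p <- pf(f, df_between, df_within, lower.tail = FALSE)
  }

  structure(
    list(
      F = f, p = p, df_between = df_between, df_within = df_within,
      mse = mse, n = nrow(df), k = k,
      group_means = df |>
        dplyr::group_by(group) |>
        dplyr::summarise(n = dplyr::n(), mean = mean(value),
                         .groups = "drop"),
      posthoc = lsd_pairs(df$value, df$group, mse, df_within),
      fit = fit
    ),
    class = "wpt_anova"
  )
}

# Fisher's LSD table from raw values and the pooled error term
lsd_pairs <- function(value, group, mse, df_within, alpha = 0.05) {
  stats_by <- tibble(value = value, group = group) |>
    dplyr::group_by(group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(value), .groups = "drop")
  pairs <- combn(as.character(stats_by$group), 2, simplify = FALSE)
  dplyr::bind_rows(lapply(pairs, function(pr) {
    a <- stats_by[stats_by$group == pr[1], ]
    b <- stats_by[stats_by$group == pr[2], ]
    se <- sqrt(mse * (1 / a$n + 1 / b$n))
    t <- if (se == 0) {
      if (a$mean == b$mean) 0 else sign(a$mean - b$mean) * Inf
    } else {
      (a$mean - b$mean) / se
    }
    p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df_within)
    tibble(group1 = pr[1], group2 = pr[2], diff = a$mean - b$mean,
           se = se, t = t, df = df_within, p = p,
           significant = p < alpha)
  }))
}

#' Fisher's LSD post-hoc comparisons
#'
#' Standalone entry point when the omnibus fit is not needed.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance flag threshold (default 0.05, two-sided).
#' @return A tibble of pairwise rows: `group1`, `group2`, `diff`, `se`,
#'   `t`, `df`, `p`, `significant`.
#' @export
lsd_posthoc <- function(data, value, group, alpha = 0.05) {
  fit <- one_way_anova(data, {{ value }}, {{ group }})
  out <- fit$posthoc
  out$significant <- out$p < alpha
  out
}

#' @export
print.wpt_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p))
  cat("Fisher's LSD pairwise comparisons:\n")
  print(x$posthoc)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.wpt_anova <- function(x, ...) x$posthoc

#' @exportS3Method generics::glance
glance.wpt_anova <- function(x, ...) {
  tibble(statistic = x$F, p_value = x$p, df_between = x$df_between,
         df_within = x$df_within, mse = x$mse, n = x$n, k = x$k)
}
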