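# Nonparametric condition contrasts: per-session baseline normalization,
# medians and inter-quartile ranges, exact Wilcoxon rank-sum, Cohen's d.

#' Compare per-session values across stimulation conditions
#'
#' Takes one value per session x condition (e.g. mean head speed per
#' epoch), normalizes each session's values to its own baseline-condition
#' value (yielding unitless ratios around 1), and contrasts two conditions
#' with distribution-free statistics: medians with inter-quartile ranges,
#' the two-sided Wilcoxon rank-sum test (exact when there are no ties,
#' midrank normal approximation otherwise), Cohen's d on the pooled SD,
#' and the percent change of medians.
#'
#' @param data A tibble with one row per session x condition.
#' @param value,condition,session Columns (tidy-eval) holding the measured
#'   value, the condition label, and the session/replicate id.
#' @param baseline Condition label used for per-session normalization, or
#'   `NULL` to compare raw values.
#' @param comparison Length-2 character: the two conditions to test;
#'   `percent_change` is the median increase of the second over the first.
#' @return A list of class `epoch_comparison`: `summary` (per-condition
#'   n/median/q1/q3), `normalized` (the per-session values used),
#'   `p_value`, `statistic`, `cohens_d`, `percent_change`, `comparison`,
#'   `baseline`.
#' @examples
#' d <- tibble::tibble(
#'   session = rep(1:6, each = 3),
#'   condition = rep(c("no_stim", "peak", "trough"), 6),
#'   value = c(t(replicate(6, c(10, 9.5, 13) + stats::rnorm(3))))
#' )
#' compare_epochs(d, value, condition, session)
#' @export
compare_epochs <- function(data, value, condition, session,
                           baseline = "no_stim",
                           comparison = c("peak", "trough")) {
  v <- rlang::enquo(value); cn <- rlang::enquo(condition); sn <- rlang::enquo(session)
  d <- dplyr::transmute(data, session = !!sn, condition = as.character(!!cn),
                        value = !!v)
  if (length(comparison) != 2)
    abort("`comparison` must name exactly two conditions", class = "phasestim_config_error")
  if (!is.null(baseline)) {
    base <- dplyr::filter(d, .data$condition == baseline)
    if (nrow(base) == 0)
      abort(paste0("baseline condition '", baseline, "' absent"), class = "phasestim_data_error")
    d <- dplyr::left_join(d, dplyr::select(base, "session", base_value = "value"),
                          by = "session")
    if (any(is.na(d$base_value)))
      abort("every session needs a baseline-condition value", class = "phasestim_data_error")
    d$value <- d$value / d$base_value
    d$base_value <- NULL
  }
  counts <- dplyr::count(dplyr::filter(d, .data$condition %in% comparison),
                         .data$condition)
  if (nrow(counts) < 2 || any(counts$n < 2))
    abort("need at least 2 sessions per compared condition", class = "phasestim_data_error")

  summ <- dplyr::summarise(
    dplyr::group_by(d, .data$condition),
    n = dplyr::n(),
    median = stats::median(.data$value),
    q1 = stats::quantile(.data$value, 0.25, names = FALSE),
    q3 = stats::quantile(.data$value, 0.75, names = FALSE),
    .groups = "drop")

  x <- d$value[d$condition == comparison[1]]
  y <- d$value[d$condition == comparison[2]]
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  pooled_sd <- sqrt(((length(x) - 1) * stats::var(x) +
                       (length(y) - 1) * stats::var(y)) /
                      (length(x) + length(y) - 2))
  cohens_d <- if (pooled_sd == 0) 0 else (mean(y) - mean(x)) / pooled_sd
  pct <- 100 * (stats::median(y) - stats::median(x)) / stats::median(x)

  structure(list(summary = summ, normalized = d,
                 p_value = wt$p.value, statistic = unname(wt$statistic),
                 cohens_d = cohens_d, percent_change = pct,
                 comparison = comparison, baseline = baseline),
            class = "epoch_comparison")
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat(sprintf("<epoch_comparison> %s vs %s%s\n", x$comparison[1], x$comparison[2],
              if (is.null(x$baseline)) "" else paste0(" (normalized to ", x$baseline, ")")))
  print(x$summary)
  cat(sprintf("rank-sum p = %.3g; Cohen's d = %.2f; %+.0f%% median change\n",
              x$p_value, x$cohens_d, x$percent_change))
  invisible(x)
}
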