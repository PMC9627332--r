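#' Days from therapy start to event onset
#'
#' Calendar-day difference between the therapy start date and the event
#' date. Both dates must have full day precision (`YYYYMMDD`): partial
#' dates are never imputed, because imputing e.g. the first of the month
#' would bias short onsets, so such records return `NA`. A negative
#' difference (event before therapy start, a data error in spontaneous
#' reports) also returns `NA`; callers count these exclusions.
#'
#' @param therapy_start,event_date Character vectors of partial-date
#'   strings.
#' @return Integer vector of onset days (`>= 0`), `NA` where unusable.
#' @examples
#' compute_onset_days("20160101", "20161231")  # 365 (2016 is a leap year)
#' compute_onset_days("201601", "20161231")    # NA: no day precision
#' @export
compute_onset_days <- function(therapy_start, event_date) {
  s <- partial_date_to_date(therapy_start)
  e <- partial_date_to_date(event_date)
  d <- as.integer(e - s)
  d[!is.na(d) & d < 0] <- NA_integer_
  d
}

#' Extract onset records from a case set
#'
#' One record per (case, ingredient) with a usable time to onset: the
#' ingredient must appear with the primary-suspect role, and the case
#' must have day-precision therapy start and event dates. When a case
#' carries several therapy start dates for the same ingredient, the
#' earliest complete date is used. The indication group is the one
#' attached to the primary-suspect drug row.
#'
#' @param caseset An `onj_caseset` (typically already restricted to event
#'   cases via [select_onj_cases()]).
#' @param ingredient Normalised ingredient name.
#' @return A list with `records` (tibble: `caseid`, `ingredient`,
#'   `indication_group`, `onset_days`) and `excluded` (named counts:
#'   `no_day_precision`, `negative`).
#' @export
onset_records <- function(caseset, ingredient) {
  d <- caseset$drugs
  d <- d[d$role_cod == "PS" & d$ingredient == ingredient, , drop = FALSE]
  ev <- setNames(caseset$cases$event_dt, caseset$cases$caseid)
  d$event_dt <- unname(ev[d$caseid])

  # earliest complete therapy start per case
  d$start_date <- partial_date_to_date(d$therapy_start)
  d <- d[order(d$caseid, d$start_date), , drop = FALSE]
  d <- d[!duplicated(d$caseid), , drop = FALSE]

  onset <- compute_onset_days(d$therapy_start, d$event_dt)
  usable_dates <- has_day_precision(d$therapy_start) &
    has_day_precision(d$event_dt)
  n_negative <- sum(usable_dates & is.na(onset))
  n_partial <- sum(!usable_dates)

  keep <- !is.na(onset)
  list(
    records = tibble::tibble(
      caseid = d$caseid[keep],
      ingredient = ingredient,
      indication_group = d$indication_group[keep],
      onset_days = onset[keep]
    ),
    excluded = c(no_day_precision = n_partial, negative = n_negative)
  )
}

#' Summarise time to onset as median (Q1, Q3)
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), the convention implied by fractional
#' printed quartiles in onset reporting.
#'
#' @param records Tibble with columns `ingredient`, `indication_group`,
#'   `onset_days` (see [onset_records()]).
#' @param by Character vector of grouping columns, default
#'   `c("ingredient", "indication_group")`.
#' @return A tibble with columns `by`, `n`, `median`, `q1`, `q3`; empty
#'   groups are absent.
#' @export
summarize_onset <- function(records,
                            by = c("ingredient", "indication_group")) {
  stopifnot(all(by %in% names(records)))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::quantile(.data$onset_days, 0.5, type = 7,
                               names = FALSE),
      q1 = stats::quantile(.data$onset_days, 0.25, type = 7,
                           names = FALSE),
      q3 = stats::quantile(.data$onset_days, 0.75, type = 7,
                           names = FALSE),
      .groups = "drop"
    )
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of onset times
#'
#' Two-sided test of a location difference between two onset-time
#' samples. The U statistic is computed from rank sums with midranks for
#' ties. The p-value is the exact permutation probability when
#' `n1 * n2 <= 400` and the pooled sample is tie-free, otherwise the
#' normal approximation with tie and continuity correction. The test is
#' delegated to [stats::wilcox.test()], which implements both routes.
#'
#' @param x,y Numeric vectors (e.g. onset days of two indication groups).
#' @return A list of class `onj_mannwhitney`: `u_statistic` (U of `x`
#'   over `y`), `p_value`, `method` (`"exact"`,
#'   `"normal_approx_tie_corrected"` or `"degenerate"`), `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y)

  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (length(unique(pooled)) == 1L) {
    return(structure(list(u_statistic = u, p_value = 1,
                          method = "degenerate", n1 = n1, n2 = n2),
                     class = "onj_mannwhitney"))
  }

  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && n1 * n2 <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  structure(
    list(u_statistic = u,
         p_value = min(1, unname(wt$p.value)),
         method = if (exact) "exact" else "normal_approx_tie_corrected",
         n1 = n1, n2 = n2),
    class = "onj_mannwhitney"
  )
}

#' @export
print.onj_mannwhitney <- function(x, ...) {
  cat("Mann-Whitney: U = ", x$u_statistic, ", p = ",
      format(x$p_value, digits = 4), " (", x$method, "; n1 = ", x$n1,
      ", n2 = ", x$n2, ")\n", sep = "")
  invisible(x)
}

#' Compare onset time between indication groups for one drug
#'
#' Runs the onset extraction, the median (Q1, Q3) summary per indication
#' group, and the Mann-Whitney comparison between two named groups.
#'
#' @inheritParams onset_records
#' @param groups The two indication groups to compare, default
#'   osteoporosis-related vs cancer-related.
#' @return A list with `summary` (tibble from [summarize_onset()]),
#'   `test` (`onj_mannwhitney` or `NULL` when either group is empty) and
#'   `excluded` counts.
#' @export
compare_onset_by_group <- function(caseset, ingredient,
                                   groups = c("OsteoporosisRelated",
                                              "CancerRelated")) {
  stopifnot(length(groups) == 2L)
  rec <- onset_records(caseset, ingredient)
  summary <- summarize_onset(rec$records)
  x <- rec$records$onset_days[rec$records$indication_group == groups[1]]
  y <- rec$records$onset_days[rec$records$indication_group == groups[2]]
  test <- if (length(x) >= 1L && length(y) >= 1L) mann_whitney(x, y)
  list(summary = summary, test = test, excluded = rec$excluded)
}
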