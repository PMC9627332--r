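#' Percentage breakdown of category counts
#'
#' Percentages are `count / sum(count) * 100`, rounded half-up to two
#' decimals (the convention used in printed report tables, where
#' `round()`'s round-half-even would differ on boundary values).
#'
#' @param counts Named integer vector, or tibble with columns `category`
#'   and `count`.
#' @return A tibble with columns `category`, `count`, `percent`.
#' @examples
#' percent_breakdown(c(F = 4149, M = 2975, Unknown = 490))
#' @export
percent_breakdown <- function(counts) {
  if (is.data.frame(counts)) {
    category <- as.character(counts$category)
    count <- as.numeric(counts$count)
  } else {
    category <- names(counts)
    count <- as.numeric(counts)
  }
  total <- sum(count)
  pct <- if (total > 0) round_half_up(count / total * 100, 2L) else
    rep(NA_real_, length(count))
  tibble::tibble(category = category, count = count, percent = pct)
}

# sex codes as printed in descriptive tables
sex_label <- function(sex) {
  out <- as.character(sex)
  out[!(out %in% c("F", "M"))] <- "Unknown"
  out
}

# indication group of the primary-suspect drug row, one label per case
ps_indication_group <- function(caseset) {
  d <- caseset$drugs
  ps <- d[d$role_cod == "PS", , drop = FALSE]
  ps <- ps[!duplicated(ps$caseid), , drop = FALSE]
  lut <- setNames(ps$indication_group, ps$caseid)
  out <- unname(lut[caseset$cases$caseid])
  out[is.na(out)] <- "Missing"
  out
}

#' Categorical descriptive breakdown of selected cases
#'
#' Tallies one variable over a set of selected cases and attaches
#' percentages. For `"outcome"` the unit is the outcome-code occurrence,
#' not the case: FAERS cases may carry several outcome codes, so outcome
#' percentages are shares of reported outcomes and need not correspond
#' one-to-one with cases.
#'
#' @param caseset An `onj_caseset` of selected cases (one ingredient).
#' @param variable One of `"sex"`, `"continent"`, `"reporter_group"`,
#'   `"indication_group"`, `"outcome"`.
#' @return A tibble with columns `variable`, `category`, `count`,
#'   `percent`.
#' @export
summarize_categorical <- function(caseset,
                                  variable = c("sex", "continent",
                                               "reporter_group",
                                               "indication_group",
                                               "outcome")) {
  variable <- match.arg(variable)
  values <- switch(
    variable,
    sex = sex_label(caseset$cases$sex),
    continent = caseset$cases$continent,
    reporter_group = caseset$cases$reporter_group,
    indication_group = ps_indication_group(caseset),
    outcome = caseset$outcomes$outc_cod
  )
  tab <- table(values)
  out <- percent_breakdown(setNames(as.integer(tab), names(tab)))
  tibble::tibble(variable = variable, out)
}

#' Age summary of selected cases
#'
#' Ages are in years (converted from the reported unit during assembly);
#' missing ages are excluded and `n` is the non-missing count. Quartiles
#' use the same linear-interpolation convention as the onset summaries.
#'
#' @param caseset An `onj_caseset` of selected cases.
#' @return A one-row tibble `n`, `median`, `q1`, `q3`, or a zero-row
#'   tibble when no case has a usable age.
#' @export
summarize_age <- function(caseset) {
  age <- caseset$cases$age_years
  age <- age[!is.na(age)]
  if (length(age) == 0L) {
    return(tibble::tibble(n = integer(0), median = numeric(0),
                          q1 = numeric(0), q3 = numeric(0)))
  }
  tibble::tibble(
    n = length(age),
    median = stats::quantile(age, 0.5, type = 7, names = FALSE),
    q1 = stats::quantile(age, 0.25, type = 7, names = FALSE),
    q3 = stats::quantile(age, 0.75, type = 7, names = FALSE)
  )
}

#' Yearly report counts
#'
#' Counts selected reports per report year, zero-filling so the series is
#' contiguous over the observed range.
#'
#' @param caseset An `onj_caseset` of selected cases.
#' @return A tibble with columns `year`, `count`; empty when no case has
#'   a report year.
#' @export
yearly_counts <- function(caseset) {
  yr <- caseset$cases$rept_yr
  yr <- yr[!is.na(yr)]
  if (length(yr) == 0L) {
    return(tibble::tibble(year = integer(0), count = integer(0)))
  }
  rng <- range(yr)
  years <- seq(rng[1], rng[2])
  tab <- table(factor(yr, levels = years))
  tibble::tibble(year = years, count = as.integer(tab))
}

#' Load the packaged descriptive-count fixture
#'
#' A small fixture with the published per-drug descriptive counts of
#' antiresorptive-related ONJ reports (sex, continent, reporter group,
#' merged indication group, outcome codes, one row per category per
#' drug), used to exercise the percentage computation against printed
#' values without any database download.
#'
#' @return A tibble with columns `ingredient`, `variable`, `category`,
#'   `count`.
#' @export
load_onj_descriptive_counts <- function() {
  path <- system.file("extdata", "onj_descriptive_counts.csv",
                      package = "onjsignal")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Percentage breakdowns for a count fixture
#'
#' Applies [percent_breakdown()] within every (ingredient, variable)
#' group of a descriptive-count table such as
#' [load_onj_descriptive_counts()].
#'
#' @param counts Tibble with columns `ingredient`, `variable`,
#'   `category`, `count`.
#' @return The input with a `percent` column appended.
#' @export
describe_counts <- function(counts) {
  counts |>
    dplyr::group_by(.data$ingredient, .data$variable) |>
    dplyr::mutate(percent = percent_breakdown(
      setNames(.data$count, .data$category))$percent) |>
    dplyr::ungroup()
}
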