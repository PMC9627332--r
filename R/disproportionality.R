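#' Stratum labels for disproportionality analysis
#'
#' Three kinds of analysis universe are supported. `stratum_none()` is the
#' unstratified analysis ("regardless of indication"): every deduplicated
#' report. `stratum_hlt(hlt)` restricts the universe to reports whose
#' primary-suspect drug carries an indication resolving to the given
#' MedDRA-style high-level term. `stratum_dose(dose_label, frequency,
#' indication_category)` is the dose-frequency-indication analysis:
#' the universe is the reports with complete dose, frequency and mapped
#' indication category on the primary-suspect drug, restricted to the
#' stratum's category; exposure additionally requires the matching dose
#' label and frequency.
#'
#' @param hlt High-level term name.
#' @param dose_label Dose label, e.g. `"4 mg"`.
#' @param frequency Frequency code, e.g. `"Q4W"`, `"Q6M"`, `"QY"`.
#' @param indication_category One of `"Osteoporosis"`, `"Malignancy"`,
#'   `"Metastasis"`, `"Prophylaxis"`.
#' @return An object of class `onj_stratum`.
#' @name strata
NULL

#' @rdname strata
#' @export
stratum_none <- function() {
  structure(list(kind = "None"), class = "onj_stratum")
}

#' @rdname strata
#' @export
stratum_hlt <- function(hlt) {
  stopifnot(is.character(hlt), length(hlt) == 1L, nzchar(hlt))
  structure(list(kind = "IndicationHLT", hlt = hlt), class = "onj_stratum")
}

#' @rdname strata
#' @export
stratum_dose <- function(dose_label, frequency, indication_category) {
  indication_category <- match.arg(
    indication_category,
    c("Osteoporosis", "Malignancy", "Metastasis", "Prophylaxis"))
  structure(list(kind = "DoseFrequencyIndication",
                 dose_label = dose_label, frequency = frequency,
                 indication_category = indication_category),
            class = "onj_stratum")
}

#' @export
format.onj_stratum <- function(x, ...) {
  switch(x$kind,
         None = "overall",
         IndicationHLT = paste0("hlt:", x$hlt),
         DoseFrequencyIndication = paste(x$dose_label, x$frequency,
                                         x$indication_category,
                                         sep = "|"))
}

#' @export
print.onj_stratum <- function(x, ...) {
  cat("<onj_stratum> ", format(x), "\n", sep = "")
  invisible(x)
}

# case ids forming the analysis universe of a stratum
stratum_universe_ids <- function(caseset, stratum) {
  d <- caseset$drugs
  ps <- d[d$role_cod == "PS", , drop = FALSE]
  switch(
    stratum$kind,
    None = caseset$cases$caseid,
    IndicationHLT =
      unique(ps$caseid[!is.na(ps$indication_hlt) &
                         ps$indication_hlt == stratum$hlt]),
    DoseFrequencyIndication = {
      complete <- !is.na(ps$dose_label) & !is.na(ps$dose_freq) &
        !is.na(ps$indication_category)
      unique(ps$caseid[complete &
                         ps$indication_category ==
                           stratum$indication_category])
    },
    stop("unknown stratum kind: ", stratum$kind, call. = FALSE)
  )
}

# case ids counting as exposed to the ingredient within a stratum
stratum_exposed_ids <- function(caseset, ingredient, stratum) {
  d <- caseset$drugs
  sel <- d$role_cod == "PS" & d$ingredient == ingredient
  if (stratum$kind == "DoseFrequencyIndication") {
    sel <- sel & !is.na(d$dose_label) & d$dose_label == stratum$dose_label &
      !is.na(d$dose_freq) & d$dose_freq == stratum$frequency &
      !is.na(d$indication_category) &
      d$indication_category == stratum$indication_category
  }
  unique(d$caseid[sel])
}

#' Build the 2x2 contingency table for one drug-event pair
#'
#' Classifies every report in the analysis universe into exactly one of
#' four cells: `a` -- the ingredient is primary suspect and the event is
#' reported; `b` -- the event is reported under other drugs; `c` -- the
#' ingredient is primary suspect with other events (including reports
#' with no coded reaction); `d` -- other drugs, other events. The cells
#' always partition the universe: `a + b + c + d` equals the number of
#' reports in the (possibly stratified) universe.
#'
#' @param caseset An `onj_caseset` (assembled, deduplicated).
#' @param ingredient Normalised ingredient name.
#' @param event_pts Integer vector of event preferred-term codes.
#' @param event_names Character vector of event PT names, used for
#'   reaction rows that carry no code.
#' @param stratum An `onj_stratum`; default unstratified.
#' @param universe `"stratum"` (default) computes all four cells within
#'   the stratum's universe; `"full"` keeps the stratum definition for
#'   exposure but draws the comparator cells `b` and `d` from all
#'   deduplicated reports.
#' @return An object of class `onj_contingency`: list with integer cells
#'   `a`, `b`, `c`, `d`, the universe size `n`, `ingredient` and
#'   `stratum`.
#' @export
build_contingency <- function(caseset, ingredient, event_pts,
                              event_names = character(),
                              stratum = stratum_none(),
                              universe = c("stratum", "full")) {
  universe <- match.arg(universe)
  stopifnot(inherits(stratum, "onj_stratum"))

  u_ids <- stratum_universe_ids(caseset, stratum)
  if (length(u_ids) == 0L) {
    stop("no reports in stratum: ", format(stratum), call. = FALSE)
  }
  exposed <- stratum_exposed_ids(caseset, ingredient, stratum)
  event <- event_caseids(caseset, event_pts, event_names)

  if (universe == "full") {
    comparator <- setdiff(caseset$cases$caseid, exposed)
  } else {
    exposed <- intersect(exposed, u_ids)
    comparator <- setdiff(u_ids, exposed)
  }

  a <- length(intersect(exposed, event))
  c_ <- length(exposed) - a
  b <- length(intersect(comparator, event))
  d <- length(comparator) - b

  structure(
    list(a = a, b = b, c = c_, d = d, n = a + b + c_ + d,
         ingredient = ingredient, stratum = stratum),
    class = "onj_contingency"
  )
}

#' @export
print.onj_contingency <- function(x, ...) {
  cat("<onj_contingency> ", x$ingredient, " [", format(x$stratum), "] ",
      "a=", x$a, " b=", x$b, " c=", x$c, " d=", x$d, "\n", sep = "")
  invisible(x)
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' The reporting odds ratio of a 2x2 report table is `ROR = (a d)/(b c)`,
#' with the log-scale (Woolf) confidence interval
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A drug-event pair
#' is flagged as a signal when `a >= 3` and the lower confidence bound is
#' strictly greater than 1.
#'
#' With any zero cell the ROR is incalculable; no continuity correction
#' is applied unless explicitly requested (`correction = "haldane"` adds
#' 0.5 to every cell). The `ci_form = "plus_one"` variant computes the
#' standard error as `sqrt(1/(a+1) + 1/(b+1) + 1/(c+1) + 1/(d+1))`; it
#' exists because typeset renderings of the interval formula are
#' ambiguous between the two forms, and the Woolf form is the default.
#'
#' @param tab An `onj_contingency`, or a numeric vector/list with
#'   elements `a`, `b`, `c`, `d`.
#' @param z Normal quantile for the interval, default 1.96 (95%).
#' @param correction `"none"` (default) or `"haldane"`.
#' @param ci_form `"woolf"` (default) or `"plus_one"`.
#' @return A one-row tibble of class `onj_signal`: `ingredient`,
#'   `stratum`, `a`, `b`, `c`, `d`, `ror`, `ci_low`, `ci_high`,
#'   `n_reports` (= `a`), `is_signal`, `incalculable`.
#' @examples
#' compute_ror(list(a = 10, b = 90, c = 100, d = 9900))
#' @export
compute_ror <- function(tab, z = 1.96, correction = c("none", "haldane"),
                        ci_form = c("woolf", "plus_one")) {
  correction <- match.arg(correction)
  ci_form <- match.arg(ci_form)

  a <- as.numeric(tab$a); b <- as.numeric(tab$b)
  c_ <- as.numeric(tab$c); d <- as.numeric(tab$d)
  stopifnot(length(a) == 1L, a >= 0, b >= 0, c_ >= 0, d >= 0)

  ingredient <- if (!is.null(tab$ingredient)) tab$ingredient else
    NA_character_
  stratum <- if (!is.null(tab$stratum)) format(tab$stratum) else "overall"

  cells <- c(a, b, c_, d)
  incalculable <- any(cells == 0)
  if (incalculable && correction == "haldane") {
    cells <- cells + 0.5
    incalculable <- FALSE
  }

  if (incalculable) {
    ror <- ci_low <- ci_high <- NA_real_
  } else {
    ror <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    se <- if (ci_form == "woolf") {
      sqrt(sum(1 / cells))
    } else {
      sqrt(sum(1 / (cells + 1)))
    }
    ci_low <- exp(log(ror) - z * se)
    ci_high <- exp(log(ror) + z * se)
  }

  out <- tibble::tibble(
    ingredient = ingredient, stratum = stratum,
    a = a, b = b, c = c_, d = d,
    ror = ror, ci_low = ci_low, ci_high = ci_high,
    n_reports = a,
    is_signal = apply_signal_criteria(a, ci_low),
    incalculable = incalculable
  )
  class(out) <- c("onj_signal", class(out))
  out
}

#' Signal criteria on a drug-event pair
#'
#' A pair is a signal when it has at least three event reports with the
#' suspect drug (`a >= 3`) and the lower bound of the 95% confidence
#' interval of the ROR is strictly greater than 1.
#'
#' @param n_reports Report count in the exposed-with-event cell (`a`), or
#'   an `onj_signal` row.
#' @param ci_low Lower confidence bound (ignored when `n_reports` is an
#'   `onj_signal`).
#' @return Logical vector.
#' @export
apply_signal_criteria <- function(n_reports, ci_low = NULL) {
  if (inherits(n_reports, "onj_signal")) {
    ci_low <- n_reports$ci_low
    n_reports <- n_reports$n_reports
  }
  !is.na(ci_low) & n_reports >= 3 & ci_low > 1
}

#' Stratified reporting odds ratios
#'
#' Computes one ROR per stratum, each from its own restricted universe.
#' Strata must be of one kind and mutually distinct; an empty stratum
#' yields a row with zero counts and `note = "no reports in stratum"`
#' rather than aborting the run.
#'
#' @inheritParams build_contingency
#' @param strata List of `onj_stratum` objects of a single kind.
#' @param ... Passed to [compute_ror()].
#' @return A tibble with one `onj_signal` row per stratum plus a `note`
#'   column.
#' @export
stratified_ror <- function(caseset, ingredient, event_pts,
                           event_names = character(), strata,
                           universe = c("stratum", "full"), ...) {
  universe <- match.arg(universe)
  stopifnot(length(strata) >= 1L,
            all(vapply(strata, inherits, logical(1), "onj_stratum")))
  kinds <- vapply(strata, `[[`, character(1), "kind")
  if (length(unique(kinds)) != 1L) {
    stop("strata must all be of the same kind", call. = FALSE)
  }
  labels <- vapply(strata, format, character(1))
  if (anyDuplicated(labels)) {
    stop("overlapping strata of the same kind: ",
         paste(labels[duplicated(labels)], collapse = ", "),
         call. = FALSE)
  }

  rows <- lapply(strata, function(s) {
    tab <- tryCatch(
      build_contingency(caseset, ingredient, event_pts, event_names,
                        stratum = s, universe = universe),
      error = function(e) NULL
    )
    if (is.null(tab)) {
      out <- tibble::tibble(
        ingredient = ingredient, stratum = format(s),
        a = 0, b = 0, c = 0, d = 0,
        ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        n_reports = 0, is_signal = FALSE, incalculable = TRUE,
        note = "no reports in stratum"
      )
      return(out)
    }
    res <- compute_ror(tab, ...)
    res$note <- if (res$incalculable) "incalculable" else ""
    res
  })
  dplyr::bind_rows(rows)
}

#' Rank signal results by reporting odds ratio
#'
#' Orders descending by ROR; ties broken by descending report count, then
#' by ingredient name. Incalculable rows sort last.
#'
#' @param results Tibble of `onj_signal` rows (possibly several
#'   ingredients).
#' @return The same tibble, reordered.
#' @export
rank_signals <- function(results) {
  if (nrow(results) == 0L) {
    return(results)
  }
  ord <- order(-xtfrm(replace(results$ror, is.na(results$ror), -Inf)),
               -xtfrm(results$n_reports),
               results$ingredient)
  results[ord, , drop = FALSE]
}

#' Overall ROR for several ingredients
#'
#' The "regardless of indication" analysis: one unstratified ROR per
#' ingredient against the full deduplicated universe, ranked.
#'
#' @inheritParams build_contingency
#' @param ingredients Character vector of ingredient names.
#' @param vocab An `onj_vocabulary` supplying the ONJ event definition.
#' @param ... Passed to [compute_ror()].
#' @return A ranked tibble of `onj_signal` rows.
#' @export
ror_overall <- function(caseset, ingredients, vocab, ...) {
  rows <- lapply(ingredients, function(ing) {
    tab <- build_contingency(caseset, ing, vocab$onj_pt_codes,
                             vocab$onj_pt_names)
    compute_ror(tab, ...)
  })
  rank_signals(dplyr::bind_rows(rows))
}
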