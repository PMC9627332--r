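#' Build a simulation configuration
#'
#' Defines the generative model of the synthetic spontaneous-report
#' generator. Each report draws one primary-suspect drug from the drug
#' mix, an indication from that drug's indication mix, a dose/frequency
#' regimen, demographics and dates; each event occurs with its background
#' probability, tilted on the odds scale by `ln(theta)` for matching
#' (drug, event, indication-group) signal rows, so a configured
#' multiplier `theta` is exactly the target odds ratio of the pair in
#' the sampled population. Therapy start precedes the event date by a
#' log-normal gap (strictly positive and right-skewed, the shape of
#' published onset-time quartiles). Case-version duplicates and partial
#' dates are injected at configurable rates.
#'
#' @param n_reports Number of distinct cases to simulate.
#' @param drugs Tibble with columns `ingredient`, `prob` (marginal
#'   probability, summing to 1), and list-columns `indications` (tibble
#'   `pt`, `prob` per drug) and `regimens` (tibble `dose_amt`,
#'   `dose_unit`, `freq`, `prob`; may be `NULL` for drugs without dose
#'   data).
#' @param events Tibble with columns `pt_cod`, `pt`, `prob` (background
#'   per-report probability).
#' @param signals Tibble with columns `ingredient`, `pt_cod`,
#'   `indication_group` (`NA` applies to all reports of the drug) and
#'   `theta` (odds multiplier, `>= 0`). May be empty (null model).
#' @param duplicate_rate Fraction of cases resubmitted as a second case
#'   version, in `[0, 1)`.
#' @param partial_date_rate Fraction of dates truncated to year-month or
#'   year precision.
#' @param missing_dose_rate,missing_indication_rate Fractions of
#'   primary-suspect rows with the dose/frequency or the indication
#'   withheld, to exercise the completeness filters.
#' @param concomitant_rate Fraction of reports carrying one additional
#'   concomitant (role `C`) drug.
#' @param companion_event Optional list `(primary_pt, companion_pt,
#'   companion_name, rate)`: reports carrying `primary_pt` additionally
#'   receive `companion_pt` at the given rate (the ONJ event has two
#'   preferred terms; selection must still count such cases once).
#' @param onset Tibble with columns `ingredient`, `indication_group`,
#'   `meanlog`, `sdlog` of the log-normal onset gap in days; pairs not
#'   listed fall back to `onset_default`.
#' @param onset_default Numeric `c(meanlog, sdlog)` fallback.
#' @param seed Integer seed; mandatory, generation is deterministic.
#' @return A validated list of class `onj_simconfig`.
#' @seealso [generate_faers_dataset()], [scenario_paperlike()]
#' @export
simulation_config <- function(n_reports,
                              drugs,
                              events,
                              signals = NULL,
                              duplicate_rate = 0,
                              partial_date_rate = 0,
                              missing_dose_rate = 0,
                              missing_indication_rate = 0,
                              concomitant_rate = 0,
                              companion_event = NULL,
                              onset = NULL,
                              onset_default = c(meanlog = log(500),
                                                sdlog = 0.8),
                              seed) {
  if (is.null(signals)) {
    signals <- tibble::tibble(ingredient = character(0),
                              pt_cod = integer(0),
                              indication_group = character(0),
                              theta = numeric(0))
  }
  cfg <- structure(
    list(n_reports = as.integer(n_reports),
         drugs = tibble::as_tibble(drugs),
         events = tibble::as_tibble(events),
         signals = tibble::as_tibble(signals),
         duplicate_rate = duplicate_rate,
         partial_date_rate = partial_date_rate,
         missing_dose_rate = missing_dose_rate,
         missing_indication_rate = missing_indication_rate,
         concomitant_rate = concomitant_rate,
         companion_event = companion_event,
         onset = onset,
         onset_default = onset_default,
         seed = if (missing(seed)) NULL else as.integer(seed)),
    class = "onj_simconfig"
  )
  problems <- validate_simulation_config(cfg)
  if (length(problems) > 0L) {
    stop("invalid simulation config:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg An `onj_simconfig` (or a bare list with the same fields).
#' @return Character vector of problems; empty when valid.
#' @export
validate_simulation_config <- function(cfg) {
  p <- character(0)
  note <- function(msg) p <<- c(p, msg)

  if (is.null(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    note("seed: a single integer seed is mandatory")
  }
  if (length(cfg$n_reports) != 1L || is.na(cfg$n_reports) ||
      cfg$n_reports < 1L) {
    note("n_reports: must be a positive integer")
  }
  d <- cfg$drugs
  if (!all(c("ingredient", "prob", "indications") %in% names(d))) {
    note("drugs: needs columns ingredient, prob, indications")
  } else {
    if (any(d$prob < 0) || abs(sum(d$prob) - 1) > 1e-8) {
      note("drugs$prob: probabilities must be >= 0 and sum to 1")
    }
    for (i in seq_len(nrow(d))) {
      mix <- d$indications[[i]]
      if (!is.null(mix) &&
          (any(mix$prob < 0) || abs(sum(mix$prob) - 1) > 1e-8)) {
        note(paste0("drugs$indications[", d$ingredient[i],
                    "]: probs must sum to 1"))
      }
    }
  }
  e <- cfg$events
  if (!all(c("pt_cod", "pt", "prob") %in% names(e))) {
    note("events: needs columns pt_cod, pt, prob")
  } else if (any(e$prob < 0 | e$prob > 1)) {
    note("events$prob: probabilities must lie in [0, 1]")
  }
  s <- cfg$signals
  if (nrow(s) > 0L && (any(!is.finite(s$theta)) || any(s$theta < 0))) {
    note("signals$theta: must be finite and >= 0")
  }
  for (r in c("duplicate_rate", "partial_date_rate", "missing_dose_rate",
              "missing_indication_rate", "concomitant_rate")) {
    v <- cfg[[r]]
    if (length(v) != 1L || is.na(v) || v < 0 || v >= 1) {
      note(paste0(r, ": must be a fraction in [0, 1)"))
    }
  }
  p
}

# sample one row index per report from a per-drug mixture list-column
sample_mixture <- function(drug_idx, mixtures, n) {
  out <- rep(NA_integer_, n)
  for (j in unique(drug_idx)) {
    mix <- mixtures[[j]]
    sel <- which(drug_idx == j)
    if (is.null(mix) || nrow(mix) == 0L) next
    out[sel] <- sample.int(nrow(mix), length(sel), replace = TRUE,
                           prob = mix$prob)
  }
  out
}

# truncate YYYYMMDD strings to month or year precision for a random subset
truncate_dates <- function(dt, rate) {
  n <- length(dt)
  hit <- runif(n) < rate
  to_year <- hit & runif(n) < 0.3
  dt[hit] <- substr(dt[hit], 1L, 6L)
  dt[to_year] <- substr(dt[to_year], 1L, 4L)
  dt
}

#' Generate a synthetic FAERS-dialect dataset with known ground truth
#'
#' Samples `n_reports` cases under the model described in
#' [simulation_config()] and emits the six FAERS-dialect tables in
#' memory, plus the ground truth: the configured odds multipliers and the
#' realized per-pair 2x2 counts, recomputed by direct classification of
#' the sampled reports (before duplicate injection). Generation is fully
#' deterministic given the config (the seed is part of the config).
#'
#' @param cfg An `onj_simconfig`.
#' @return A list with elements `tables` (named list `demo`, `drug`,
#'   `reac`, `indi`, `ther`, `outc` of tibbles matching the dialect
#'   layouts) and `ground_truth` (list: `signals` as configured,
#'   `realized` tibble of per-(ingredient, event) cells and odds ratios).
#' @export
generate_faers_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "onj_simconfig"))
  set.seed(cfg$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")

  n <- cfg$n_reports
  nd <- nrow(cfg$drugs)
  drug_idx <- sample.int(nd, n, replace = TRUE, prob = cfg$drugs$prob)
  ingredient <- cfg$drugs$ingredient[drug_idx]

  ind_row <- sample_mixture(drug_idx, cfg$drugs$indications, n)
  indication <- rep(NA_character_, n)
  for (j in unique(drug_idx)) {
    mix <- cfg$drugs$indications[[j]]
    if (is.null(mix)) next
    sel <- which(drug_idx == j & !is.na(ind_row))
    indication[sel] <- mix$pt[ind_row[sel]]
  }
  indication[runif(n) < cfg$missing_indication_rate] <- NA_character_
  ind_group <- merge_indication_groups(indication)

  reg <- if ("regimens" %in% names(cfg$drugs)) cfg$drugs$regimens else
    rep(list(NULL), nd)
  reg_row <- sample_mixture(drug_idx, reg, n)
  dose_amt <- rep(NA_real_, n)
  dose_unit <- dose_freq <- rep(NA_character_, n)
  for (j in unique(drug_idx)) {
    r <- reg[[j]]
    if (is.null(r)) next
    sel <- which(drug_idx == j & !is.na(reg_row))
    dose_amt[sel] <- r$dose_amt[reg_row[sel]]
    dose_unit[sel] <- r$dose_unit[reg_row[sel]]
    dose_freq[sel] <- r$freq[reg_row[sel]]
  }
  drop_dose <- runif(n) < cfg$missing_dose_rate
  dose_amt[drop_dose] <- NA_real_
  dose_unit[drop_dose] <- dose_freq[drop_dose] <- NA_character_

  # event occurrence: background logit shifted by ln(theta) where a
  # signal row matches the report's drug (and indication group, if set)
  ne <- nrow(cfg$events)
  occ <- matrix(FALSE, n, ne)
  for (e in seq_len(ne)) {
    lt <- rep(0, n)
    sig <- cfg$signals[cfg$signals$pt_cod == cfg$events$pt_cod[e], ,
                       drop = FALSE]
    if (nrow(sig) > 0L) {
      for (k in seq_len(nrow(sig))) {
        hit <- ingredient == sig$ingredient[k]
        if (!is.na(sig$indication_group[k])) {
          hit <- hit & ind_group == sig$indication_group[k]
        }
        lt[hit] <- lt[hit] + log(sig$theta[k])
      }
    }
    pr <- plogis(qlogis(cfg$events$prob[e]) + lt)
    occ[, e] <- runif(n) < pr
  }

  # dates: event date uniform over 2004-01-01 .. 2021-09-30; therapy
  # start precedes it by a log-normal gap drawn per (drug, group)
  d0 <- as.Date("2004-01-01")
  d1 <- as.Date("2021-09-30")
  event_date <- d0 + sample.int(as.integer(d1 - d0) + 1L, n,
                                replace = TRUE) - 1L
  meanlog <- rep(cfg$onset_default[[1]], n)
  sdlog <- rep(cfg$onset_default[[2]], n)
  if (!is.null(cfg$onset)) {
    for (k in seq_len(nrow(cfg$onset))) {
      hit <- ingredient == cfg$onset$ingredient[k] &
        ind_group == cfg$onset$indication_group[k]
      meanlog[hit] <- cfg$onset$meanlog[k]
      sdlog[hit] <- cfg$onset$sdlog[k]
    }
  }
  gap <- pmax(0L, as.integer(round(rlnorm(n, meanlog, sdlog))))
  start_date <- event_date - gap

  event_dt <- truncate_dates(format(event_date, "%Y%m%d"),
                             cfg$partial_date_rate)
  start_dt <- truncate_dates(format(start_date, "%Y%m%d"),
                             cfg$partial_date_rate)
  rept_yr <- as.integer(format(event_date, "%Y"))

  # demographics
  sex <- sample(c("F", "M", "UNK"), n, replace = TRUE,
                prob = c(0.55, 0.35, 0.10))
  age <- round(rnorm(n, 68, 10), 0)
  age[age < 18] <- 18
  age_cod <- rep("YR", n)
  age[runif(n) < 0.05] <- NA_real_
  country <- sample(c("US", "CA", "GB", "DE", "FR", "IT", "JP", "BR",
                      "AU", "ZA", "XX"), n, replace = TRUE,
                    prob = c(0.30, 0.05, 0.10, 0.10, 0.08, 0.07, 0.10,
                             0.06, 0.05, 0.04, 0.05))
  occp <- sample(c("MD", "OT", "CN", "PH", "LW", "UNK"), n,
                 replace = TRUE,
                 prob = c(0.30, 0.30, 0.20, 0.08, 0.02, 0.10))

  caseid <- sprintf("C%07d", seq_len(n))
  primaryid <- paste0(caseid, ".1")

  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid, caseversion = 1L,
    event_dt = event_dt,
    age = age, age_cod = ifelse(is.na(age), "", age_cod),
    sex = sex, occp_cod = occp, reporter_country = country,
    rept_yr = rept_yr
  )

  drug <- tibble::tibble(
    primaryid = primaryid, drug_seq = 1L, role_cod = "PS",
    drugname = toupper(ingredient),
    dose_amt = dose_amt,
    dose_unit = ifelse(is.na(dose_unit), "", dose_unit),
    dose_freq = ifelse(is.na(dose_freq), "", dose_freq)
  )
  conc <- which(runif(n) < cfg$concomitant_rate)
  if (length(conc) > 0L) {
    conc_idx <- sample.int(nd, length(conc), replace = TRUE,
                           prob = cfg$drugs$prob)
    drug <- dplyr::bind_rows(drug, tibble::tibble(
      primaryid = primaryid[conc], drug_seq = 2L, role_cod = "C",
      drugname = toupper(cfg$drugs$ingredient[conc_idx]),
      dose_amt = NA_real_, dose_unit = "", dose_freq = ""
    ))
  }

  reac_rows <- which(occ, arr.ind = TRUE)
  reac <- tibble::tibble(
    primaryid = primaryid[reac_rows[, 1]],
    pt_cod = as.integer(cfg$events$pt_cod[reac_rows[, 2]]),
    pt = cfg$events$pt[reac_rows[, 2]]
  )
  ce <- cfg$companion_event
  if (!is.null(ce)) {
    carriers <- which(occ[, match(ce$primary_pt, cfg$events$pt_cod)])
    extra <- carriers[runif(length(carriers)) < ce$rate]
    if (length(extra) > 0L) {
      reac <- dplyr::bind_rows(reac, tibble::tibble(
        primaryid = primaryid[extra],
        pt_cod = as.integer(ce$companion_pt),
        pt = ce$companion_name
      ))
    }
  }

  indi <- tibble::tibble(
    primaryid = primaryid[!is.na(indication)],
    indi_drug_seq = 1L,
    indi_pt = indication[!is.na(indication)]
  )
  ther <- tibble::tibble(
    primaryid = primaryid, dsg_drug_seq = 1L, start_dt = start_dt
  )
  n_outc <- rbinom(n, 2L, 0.35)
  outc_case <- rep(seq_len(n), n_outc)
  outc <- tibble::tibble(
    primaryid = primaryid[outc_case],
    outc_cod = sample(outcome_codes, length(outc_case), replace = TRUE,
                      prob = c(0.05, 0.10, 0.25, 0.03, 0.01, 0.01, 0.55))
  )

  # duplicate injection: resubmit a fraction of cases as version 2 with
  # identical content under a new primaryid
  n_dup <- as.integer(round(cfg$duplicate_rate * n))
  if (n_dup > 0L) {
    dup <- sample.int(n, n_dup)
    new_id <- paste0(caseid[dup], ".2")
    remap <- setNames(new_id, primaryid[dup])
    clone <- function(tb) {
      cl <- tb[tb$primaryid %in% names(remap), , drop = FALSE]
      cl$primaryid <- unname(remap[cl$primaryid])
      cl
    }
    demo2 <- clone(demo)
    demo2$caseversion <- 2L
    demo <- dplyr::bind_rows(demo, demo2)
    drug <- dplyr::bind_rows(drug, clone(drug))
    reac <- dplyr::bind_rows(reac, clone(reac))
    indi <- dplyr::bind_rows(indi, clone(indi))
    ther <- dplyr::bind_rows(ther, clone(ther))
    outc <- dplyr::bind_rows(outc, clone(outc))
  }

  # ground truth: realized 2x2 cells per configured (ingredient, event)
  # pair by direct classification of the sampled reports
  pairs <- unique(cfg$signals[, c("ingredient", "pt_cod")])
  realized <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(k) {
    exp_ <- ingredient == pairs$ingredient[k]
    ev <- occ[, match(pairs$pt_cod[k], cfg$events$pt_cod)]
    a <- sum(exp_ & ev); b <- sum(!exp_ & ev)
    c_ <- sum(exp_ & !ev); d <- sum(!exp_ & !ev)
    tibble::tibble(ingredient = pairs$ingredient[k],
                   pt_cod = pairs$pt_cod[k],
                   a = a, b = b, c = c_, d = d,
                   odds_ratio = (a * d) / (b * c_))
  }))

  list(
    tables = list(demo = demo, drug = drug, reac = reac, indi = indi,
                  ther = ther, outc = outc),
    ground_truth = list(signals = cfg$signals, realized = realized)
  )
}

#' A packaged scenario mirroring the antiresorptive-ONJ study structure
#'
#' Eight antiresorptive ingredients plus a comparator pool of
#' non-antiresorptive drugs, indication mixes spanning the two merged
#' indication families, the four dose/frequency regimens of the
#' dose-stratified analysis ("4 mg" Q4W and "5 mg" QY zoledronic acid,
#' "120 mg" Q4W and "60 mg" Q6M denosumab), ONJ odds multipliers that are
#' large for bisphosphonates and modest for romosozumab, stratum-specific
#' multipliers so indication strata separate, duplicates, partial dates
#' and a companion "exposed bone in jaw" preferred term. The defaults
#' exercise every pipeline stage at a desk-scale problem size.
#'
#' @param n_reports Number of cases (default 8000).
#' @param seed Integer seed.
#' @return An `onj_simconfig`.
#' @export
scenario_paperlike <- function(n_reports = 8000, seed = 20210930) {
  mix <- function(...) {
    m <- rbind(...)
    tibble::tibble(pt = m[, 1], prob = as.numeric(m[, 2]))
  }
  regs <- function(...) {
    m <- rbind(...)
    tibble::tibble(dose_amt = as.numeric(m[, 1]), dose_unit = m[, 2],
                   freq = m[, 3], prob = as.numeric(m[, 4]))
  }
  onc_mix <- mix(c("metastases to bone", "0.40"),
                 c("breast cancer", "0.15"),
                 c("prostate cancer", "0.10"),
                 c("multiple myeloma", "0.10"),
                 c("neoplasm malignant", "0.05"),
                 c("osteoporosis", "0.15"),
                 c("osteoporosis postmenopause", "0.05"))
  op_mix <- mix(c("osteoporosis", "0.55"),
                c("osteoporosis postmenopause", "0.25"),
                c("osteopenia", "0.10"),
                c("osteoporosis prophylaxis", "0.05"),
                c("breast cancer", "0.05"))
  deno_mix <- mix(c("metastases to bone", "0.30"),
                  c("breast cancer", "0.10"),
                  c("neoplasm malignant", "0.08"),
                  c("osteoporosis", "0.27"),
                  c("osteoporosis postmenopause", "0.10"),
                  c("osteoporosis prophylaxis", "0.15"))
  other_mix <- mix(c("hypertension", "0.4"),
                   c("diabetes mellitus", "0.3"),
                   c("asthma", "0.3"))

  drugs <- tibble::tibble(
    ingredient = c("zoledronic acid", "alendronate", "denosumab",
                   "risedronate", "ibandronate", "pamidronate",
                   "romosozumab", "etidronate",
                   "metformin", "lisinopril", "atorvastatin"),
    prob = c(0.10, 0.07, 0.10, 0.03, 0.03, 0.025, 0.01, 0.005,
             0.22, 0.21, 0.20),
    indications = list(onc_mix, op_mix, deno_mix, op_mix, op_mix,
                       onc_mix, op_mix, op_mix,
                       other_mix, other_mix, other_mix),
    regimens = list(
      regs(c("4", "mg", "Q4W", "0.75"), c("5", "mg", "QY", "0.25")),
      regs(c("70", "mg", "QW", "1")),
      regs(c("120", "mg", "Q4W", "0.55"), c("60", "mg", "Q6M", "0.45")),
      regs(c("35", "mg", "QW", "1")),
      regs(c("150", "mg", "QM", "1")),
      regs(c("90", "mg", "Q4W", "1")),
      regs(c("210", "mg", "QM", "1")),
      regs(c("400", "mg", "QD", "1")),
      NULL, NULL, NULL
    )
  )

  events <- tibble::tibble(
    pt_cod = c(10064658L, 10028813L, 10037660L, 10003239L),
    pt = c("osteonecrosis of the jaw", "nausea", "pyrexia", "arthralgia"),
    prob = c(0.004, 0.15, 0.10, 0.08)
  )

  onj <- 10064658L
  signals <- tibble::tibble(
    ingredient = c("pamidronate", "zoledronic acid", "zoledronic acid",
                   "denosumab", "denosumab", "alendronate", "risedronate",
                   "etidronate", "ibandronate", "romosozumab"),
    pt_cod = onj,
    indication_group = c(NA, "CancerRelated", "OsteoporosisRelated",
                         "CancerRelated", "OsteoporosisRelated",
                         NA, NA, NA, NA, NA),
    theta = c(120, 110, 12, 60, 25, 40, 35, 18, 12, 3)
  )

  onset <- tibble::tibble(
    ingredient = rep(c("zoledronic acid", "denosumab", "ibandronate",
                       "risedronate", "romosozumab", "pamidronate"),
                     each = 2),
    indication_group = rep(c("OsteoporosisRelated", "CancerRelated"), 6),
    meanlog = log(c(730, 680, 490, 488, 720, 700, 760, 700, 150, 150,
                    700, 696)),
    sdlog = rep(0.85, 12)
  )

  simulation_config(
    n_reports = n_reports,
    drugs = drugs,
    events = events,
    signals = signals,
    duplicate_rate = 0.05,
    partial_date_rate = 0.15,
    missing_dose_rate = 0.25,
    missing_indication_rate = 0.10,
    concomitant_rate = 0.30,
    companion_event = list(primary_pt = onj, companion_pt = 10071014L,
                           companion_name = "exposed bone in jaw",
                           rate = 0.10),
    onset = onset,
    seed = seed
  )
}
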