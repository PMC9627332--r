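# shared builders for hand-made raw tables and simulation configs

demo_row <- function(primaryid, caseid = primaryid, caseversion = 1L,
                     event_dt = "20160601", age = 70, age_cod = "YR",
                     sex = "F", occp_cod = "MD", country = "US",
                     rept_yr = 2016L) {
  tibble::tibble(primaryid = primaryid, caseid = caseid,
                 caseversion = as.integer(caseversion),
                 event_dt = event_dt, age = age, age_cod = age_cod,
                 sex = sex, occp_cod = occp_cod,
                 reporter_country = country,
                 rept_yr = as.integer(rept_yr))
}

drug_row <- function(primaryid, drugname, role_cod = "PS", drug_seq = 1L,
                     dose_amt = NA_real_, dose_unit = "", dose_freq = "") {
  tibble::tibble(primaryid = primaryid, drug_seq = as.integer(drug_seq),
                 role_cod = role_cod, drugname = drugname,
                 dose_amt = dose_amt, dose_unit = dose_unit,
                 dose_freq = dose_freq)
}

reac_row <- function(primaryid, pt_cod = 10064658L,
                     pt = "osteonecrosis of the jaw") {
  tibble::tibble(primaryid = primaryid, pt_cod = as.integer(pt_cod),
                 pt = pt)
}

empty_tables <- function() {
  list(
    demo = demo_row(character(0)),
    drug = drug_row(character(0), character(0)),
    reac = reac_row(character(0)),
    indi = tibble::tibble(primaryid = character(0),
                          indi_drug_seq = integer(0),
                          indi_pt = character(0)),
    ther = tibble::tibble(primaryid = character(0),
                          dsg_drug_seq = integer(0),
                          start_dt = character(0)),
    outc = tibble::tibble(primaryid = character(0),
                          outc_cod = character(0))
  )
}

# merge user-supplied tables over the empty skeleton
make_tables <- function(...) {
  out <- empty_tables()
  given <- list(...)
  for (nm in names(given)) out[[nm]] <- given[[nm]]
  out
}

test_vocab <- function() load_vocabulary()

# minimal clean config for odds-ratio parameter recovery: one signal
# drug against a non-signal comparator pool, one event, no noise
recovery_config <- function(theta, n, seed, exposed_prob = 0.15,
                            event_prob = 0.01) {
  drugs <- tibble::tibble(
    ingredient = c("zoledronic acid", "metformin", "lisinopril"),
    prob = c(exposed_prob, (1 - exposed_prob) * 0.55,
             (1 - exposed_prob) * 0.45),
    indications = list(
      tibble::tibble(pt = "osteoporosis", prob = 1),
      tibble::tibble(pt = "hypertension", prob = 1),
      tibble::tibble(pt = "hypertension", prob = 1)
    ),
    regimens = list(NULL, NULL, NULL)
  )
  events <- tibble::tibble(pt_cod = 10064658L,
                           pt = "osteonecrosis of the jaw",
                           prob = event_prob)
  signals <- tibble::tibble(ingredient = "zoledronic acid",
                            pt_cod = 10064658L,
                            indication_group = NA_character_,
                            theta = theta)
  simulation_config(n_reports = n, drugs = drugs, events = events,
                    signals = signals, seed = seed)
}

# independent brute-force classification of a case set into the 2x2
# cells: a per-case loop over pre-split row indexes, sharing no set
# logic with build_contingency
brute_force_cells <- function(caseset, ingredient, event_pts,
                              event_names = character(),
                              stratum = NULL) {
  dtab <- caseset$drugs
  rtab <- caseset$reactions
  drug_idx <- split(seq_len(nrow(dtab)), dtab$caseid)
  reac_idx <- split(seq_len(nrow(rtab)), rtab$caseid)

  a <- b <- c_ <- d <- 0L
  for (cid in caseset$cases$caseid) {
    di <- drug_idx[[cid]]
    ps <- di[dtab$role_cod[di] == "PS"]

    if (!is.null(stratum)) {
      member <- if (stratum$kind == "IndicationHLT") {
        any(!is.na(dtab$indication_hlt[ps]) &
              dtab$indication_hlt[ps] == stratum$hlt)
      } else {
        any(!is.na(dtab$dose_label[ps]) & !is.na(dtab$dose_freq[ps]) &
              !is.na(dtab$indication_category[ps]) &
              dtab$indication_category[ps] == stratum$indication_category)
      }
      if (!member) next
    }

    mine <- ps[dtab$ingredient[ps] == ingredient]
    e <- length(mine) > 0L
    if (e && !is.null(stratum) &&
        stratum$kind == "DoseFrequencyIndication") {
      e <- any(!is.na(dtab$dose_label[mine]) &
                 dtab$dose_label[mine] == stratum$dose_label &
                 !is.na(dtab$dose_freq[mine]) &
                 dtab$dose_freq[mine] == stratum$frequency &
                 !is.na(dtab$indication_category[mine]) &
                 dtab$indication_category[mine] ==
                   stratum$indication_category)
    }

    ri <- reac_idx[[cid]]
    v <- !is.null(ri) &&
      any((!is.na(rtab$pt_cod[ri]) & rtab$pt_cod[ri] %in% event_pts) |
            (is.na(rtab$pt_cod[ri]) & !is.na(rtab$pt[ri]) &
               rtab$pt[ri] %in% tolower(event_names)))

    if (e && v) a <- a + 1L
    else if (!e && v) b <- b + 1L
    else if (e && !v) c_ <- c_ + 1L
    else d <- d + 1L
  }
  list(a = a, b = b, c = c_, d = d)
}
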