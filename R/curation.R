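#' Deduplicate case versions
#'
#' FAERS cases are resubmitted as new versions (follow-ups, manufacturer
#' duplicates); every analysis counts a case once. For each `caseid` the
#' record with the highest `caseversion` is kept; ties are broken by the
#' latest `rept_yr`, then by the lexicographically largest `primaryid`.
#' The operation is idempotent.
#'
#' @param demo Tibble of DEMO records (see [faers-dialect]).
#' @return Tibble with exactly one row per `caseid`.
#' @export
deduplicate_cases <- function(demo) {
  if (nrow(demo) == 0L) {
    return(demo)
  }
  ord <- order(demo$caseid,
               -xtfrm(demo$caseversion),
               -xtfrm(demo$rept_yr),
               -xtfrm(demo$primaryid))
  demo <- demo[ord, , drop = FALSE]
  demo[!duplicated(demo$caseid), , drop = FALSE]
}

#' Default indication-merging rule lists
#'
#' Two mergers are used downstream, both configurable term lists rather
#' than hard-coded logic. `indication_group` collapses indications to
#' osteoporosis-related vs cancer-related for the onset analysis;
#' `indication_category` collapses them to
#' osteoporosis/malignancy/metastasis/prophylaxis for the
#' dose-frequency-stratified signal analysis, where prophylaxis stays its
#' own category. Matching is case-insensitive and term-exact. The
#' osteoporosis list deliberately contains both "osteopetrosis" and
#' "osteoporosis": the source merging lists name osteopetrosis, which may
#' be a transcription slip for osteoporosis, so both are included rather
#' than silently correcting either.
#'
#' @return A list with elements `group` (lists `osteoporosis_related`,
#'   `cancer_related`) and `category` (lists `osteoporosis`, `malignancy`,
#'   `metastasis`, `prophylaxis`).
#' @export
default_indication_rules <- function() {
  list(
    group = list(
      osteoporosis_related = c(
        "osteoporosis", "osteopetrosis", "osteoporosis postmenopause",
        "postmenopause", "osteoporosis prophylaxis", "osteopenia"
      ),
      cancer_related = c(
        "metastases to bone", "prostate cancer", "breast cancer",
        "neoplasm malignant", "plasma cell myeloma", "multiple myeloma",
        "breast cancer metastatic", "prostate cancer metastatic",
        "metastases to breast", "metastases to prostate", "metastasis",
        "metastatic neoplasm"
      )
    ),
    category = list(
      osteoporosis = c(
        "osteoporosis", "osteopetrosis", "osteoporosis postmenopause",
        "postmenopause", "osteopenia"
      ),
      malignancy = c(
        "prostate cancer", "breast cancer", "neoplasm malignant"
      ),
      metastasis = c(
        "metastases to bone", "metastases to breast",
        "metastases to prostate", "breast cancer metastatic",
        "prostate cancer metastatic", "metastasis", "metastatic neoplasm"
      ),
      prophylaxis = c("osteoporosis prophylaxis", "prophylaxis")
    )
  )
}

#' Merge indication preferred terms into broad indication groups
#'
#' Collapses indication PTs into `"OsteoporosisRelated"`,
#' `"CancerRelated"` or `"Other"`; absent PTs map to `"Missing"`.
#'
#' @param pt Character vector of indication preferred terms (`NA` or `""`
#'   for absent).
#' @param rules Rule lists, by default [default_indication_rules()].
#' @return Character vector of group labels.
#' @export
merge_indication_groups <- function(pt, rules = default_indication_rules()) {
  key <- tolower(trimws(as.character(pt)))
  out <- rep("Other", length(key))
  out[key %in% tolower(rules$group$osteoporosis_related)] <-
    "OsteoporosisRelated"
  out[key %in% tolower(rules$group$cancer_related)] <- "CancerRelated"
  out[is.na(key) | !nzchar(key)] <- "Missing"
  out
}

#' Merge indication preferred terms into dose-analysis categories
#'
#' Categories for the dose-frequency-indication stratified analysis:
#' `"Osteoporosis"`, `"Malignancy"`, `"Metastasis"`, `"Prophylaxis"`.
#' Prophylaxis terms are kept as their own category rather than merged
#' into osteoporosis. Terms outside every list return `NA`, which marks
#' the record for exclusion (the dose-stratified analysis drops any case
#' with missing dose, frequency or indication).
#'
#' @inheritParams merge_indication_groups
#' @return Character vector of category labels, `NA` where unmapped.
#' @export
merge_dose_indication_categories <- function(pt,
                                             rules = default_indication_rules()) {
  key <- tolower(trimws(as.character(pt)))
  out <- rep(NA_character_, length(key))
  out[key %in% tolower(rules$category$osteoporosis)] <- "Osteoporosis"
  out[key %in% tolower(rules$category$malignancy)] <- "Malignancy"
  out[key %in% tolower(rules$category$metastasis)] <- "Metastasis"
  out[key %in% tolower(rules$category$prophylaxis)] <- "Prophylaxis"
  out
}

reporter_group_map <- c(MD = "Physician", OT = "OtherHealthProfessional",
                        CN = "Consumer", PH = "Pharmacist", LW = "Lawyer")

#' Map reporter occupation codes to reporter groups
#'
#' @param occp_cod Character vector of occupation codes.
#' @return Character vector: `Physician`, `OtherHealthProfessional`,
#'   `Consumer`, `Pharmacist`, `Lawyer` or `Unknown`.
#' @export
reporter_group <- function(occp_cod) {
  out <- unname(reporter_group_map[as.character(occp_cod)])
  out[is.na(out)] <- "Unknown"
  out
}

#' Map country codes to continents
#'
#' Uses the packaged country-to-continent table; unknown or missing
#' countries map to `"Unknown"`. One country field is exposed per report
#' (the reporter country), the only geography FAERS reliably carries.
#'
#' @param country Character vector of country codes.
#' @param table Optional two-column data frame (`country`, `continent`)
#'   overriding the packaged table.
#' @return Character vector of continent labels.
#' @export
country_to_continent <- function(country, table = NULL) {
  if (is.null(table)) {
    table <- utils::read.csv(
      system.file("extdata", "country_continent.csv", package = "onjsignal"),
      stringsAsFactors = FALSE
    )
  }
  lut <- setNames(table$continent, toupper(table$country))
  out <- unname(lut[toupper(trimws(as.character(country)))])
  out[is.na(out)] <- "Unknown"
  out
}

#' Convert reported ages to years
#'
#' @param age Numeric vector of reported ages.
#' @param age_cod Unit codes: `DEC`/`YR` (years), `MON` (months), `DY`
#'   (days); anything else gives `NA`.
#' @return Numeric vector of ages in years.
#' @export
age_to_years <- function(age, age_cod) {
  f <- c(DEC = 1, YR = 1, MON = 1 / 12, DY = 1 / 365.25)
  mult <- unname(f[as.character(age_cod)])
  age * mult
}

#' Assemble an analysis-ready case set
#'
#' Joins the six raw tables into one relational case set keyed by
#' `caseid`: the deduplicated DEMO rows become the case table, DRUG rows
#' gain their THER therapy-start date and INDI indication (joined on drug
#' sequence number), verbatim drug names are normalised to ingredients,
#' and indications are resolved to high-level terms, broad indication
#' groups, and dose-analysis categories. Reports with zero reactions are
#' retained -- they populate the non-event cells of the contingency
#' tables. Child rows whose `primaryid` matches no deduplicated DEMO row
#' (orphans, including rows attached to superseded case versions) are
#' counted in the assembly log, never fatal.
#'
#' @param tables Named list of record tibbles (`demo`, `drug`, `reac`,
#'   `indi`, `ther`, `outc`).
#' @param vocab An `onj_vocabulary` from [load_vocabulary()].
#' @param rules Indication rule lists, see [default_indication_rules()].
#' @param deduplicate Deduplicate DEMO first (default `TRUE`).
#' @return An object of class `onj_caseset`: a list of tibbles `cases`
#'   (one row per case: `caseid`, `primaryid`, `event_dt`, `rept_yr`,
#'   `sex`, `age_years`, `reporter_group`, `continent`), `drugs`,
#'   `reactions`, `outcomes`, plus an assembly `log` (named counts).
#' @export
assemble_cases <- function(tables, vocab, rules = default_indication_rules(),
                           deduplicate = TRUE) {
  demo <- tables$demo
  if (deduplicate) {
    demo <- deduplicate_cases(demo)
  }

  cases <- tibble::tibble(
    caseid = demo$caseid,
    primaryid = demo$primaryid,
    event_dt = demo$event_dt,
    rept_yr = demo$rept_yr,
    sex = ifelse(nzchar(demo$sex), demo$sex, "UNK"),
    age_years = age_to_years(demo$age, demo$age_cod),
    reporter_group = reporter_group(demo$occp_cod),
    continent = country_to_continent(demo$reporter_country)
  )

  keep_id <- demo$primaryid
  id2case <- setNames(demo$caseid, demo$primaryid)

  drug <- tables$drug
  orphan_drug <- sum(!(drug$primaryid %in% keep_id))
  drug <- drug[drug$primaryid %in% keep_id, , drop = FALSE]

  indi <- tables$indi
  orphan_indi <- sum(!(indi$primaryid %in% keep_id))
  indi <- indi[indi$primaryid %in% keep_id, , drop = FALSE]

  ther <- tables$ther
  orphan_ther <- sum(!(ther$primaryid %in% keep_id))
  ther <- ther[ther$primaryid %in% keep_id, , drop = FALSE]

  norm <- normalize_drug_names(drug$drugname, vocab)
  drugs <- tibble::tibble(
    caseid = unname(id2case[drug$primaryid]),
    primaryid = drug$primaryid,
    drug_seq = drug$drug_seq,
    role_cod = drug$role_cod,
    verbatim = drug$drugname,
    ingredient = norm$ingredient,
    ingredient_mapped = norm$mapped,
    dose_amt = drug$dose_amt,
    dose_unit = ifelse(nzchar(drug$dose_unit), drug$dose_unit,
                       NA_character_),
    dose_freq = ifelse(nzchar(drug$dose_freq), drug$dose_freq,
                       NA_character_)
  )
  drugs <- dplyr::left_join(
    drugs,
    tibble::tibble(primaryid = ther$primaryid,
                   drug_seq = ther$dsg_drug_seq,
                   therapy_start = ther$start_dt),
    by = c("primaryid", "drug_seq")
  )
  drugs <- dplyr::left_join(
    drugs,
    tibble::tibble(primaryid = indi$primaryid,
                   drug_seq = indi$indi_drug_seq,
                   indication_pt = ifelse(nzchar(indi$indi_pt),
                                          indi$indi_pt, NA_character_)),
    by = c("primaryid", "drug_seq")
  )
  drugs$indication_hlt <- pt_to_hlt(drugs$indication_pt, vocab)
  drugs$indication_group <- merge_indication_groups(drugs$indication_pt,
                                                    rules)
  drugs$indication_category <-
    merge_dose_indication_categories(drugs$indication_pt, rules)
  drugs$dose_label <- ifelse(
    is.na(drugs$dose_amt) | is.na(drugs$dose_unit), NA_character_,
    paste(format(drugs$dose_amt, trim = TRUE, scientific = FALSE),
          drugs$dose_unit)
  )

  reac <- tables$reac
  orphan_reac <- sum(!(reac$primaryid %in% keep_id))
  reac <- reac[reac$primaryid %in% keep_id, , drop = FALSE]
  reactions <- tibble::tibble(
    caseid = unname(id2case[reac$primaryid]),
    pt_cod = reac$pt_cod,
    pt = tolower(ifelse(nzchar(reac$pt), reac$pt, NA_character_))
  )

  outc <- tables$outc
  orphan_outc <- sum(!(outc$primaryid %in% keep_id))
  outc <- outc[outc$primaryid %in% keep_id, , drop = FALSE]
  outcomes <- tibble::tibble(
    caseid = unname(id2case[outc$primaryid]),
    outc_cod = outc$outc_cod
  )

  structure(
    list(
      cases = cases, drugs = drugs, reactions = reactions,
      outcomes = outcomes,
      log = c(n_cases = nrow(cases),
              orphan_drug = orphan_drug, orphan_reac = orphan_reac,
              orphan_indi = orphan_indi, orphan_ther = orphan_ther,
              orphan_outc = orphan_outc,
              unmapped_drug_rows = sum(!drugs$ingredient_mapped))
    ),
    class = "onj_caseset"
  )
}

#' @export
print.onj_caseset <- function(x, ...) {
  cat("<onj_caseset> ", nrow(x$cases), " cases, ",
      nrow(x$drugs), " drug rows, ",
      nrow(x$reactions), " reaction rows\n", sep = "")
  invisible(x)
}

#' Subset a case set to a vector of case ids
#'
#' @param caseset An `onj_caseset`.
#' @param caseids Character vector of case ids to keep.
#' @return The filtered `onj_caseset`.
#' @export
filter_caseset <- function(caseset, caseids) {
  out <- caseset
  out$cases <- caseset$cases[caseset$cases$caseid %in% caseids, ,
                             drop = FALSE]
  for (tb in c("drugs", "reactions", "outcomes")) {
    out[[tb]] <- caseset[[tb]][caseset[[tb]]$caseid %in% caseids, ,
                               drop = FALSE]
  }
  out
}

# case ids whose reactions match the event definition: PT code when
# present, else case-insensitive PT name
event_caseids <- function(caseset, event_pts, event_names = character()) {
  r <- caseset$reactions
  hit <- (!is.na(r$pt_cod) & r$pt_cod %in% event_pts) |
    (is.na(r$pt_cod) & !is.na(r$pt) & r$pt %in% tolower(event_names))
  unique(r$caseid[hit])
}

# case ids carrying the ingredient with the primary-suspect role
ps_caseids <- function(caseset, ingredient) {
  d <- caseset$drugs
  unique(d$caseid[d$role_cod == "PS" & d$ingredient == ingredient])
}

#' Select ONJ cases for one ingredient
#'
#' A case is selected when (1) any of its reactions matches the ONJ event
#' definition -- preferred-term code 10064658 ("osteonecrosis of the jaw")
#' or 10071014 ("exposed bone in jaw"), by code when coded, else by
#' case-insensitive name -- and (2) the named ingredient appears on the
#' case with the primary-suspect (PS) role. A case with both event PTs is
#' counted once.
#'
#' @param caseset An `onj_caseset`.
#' @param vocab An `onj_vocabulary`.
#' @param ingredient Normalised ingredient name, e.g. `"zoledronic acid"`.
#' @return The selected cases as an `onj_caseset` (possibly empty); an
#'   ingredient absent from the data yields an empty result with a
#'   warning.
#' @export
select_onj_cases <- function(caseset, vocab, ingredient) {
  if (!(ingredient %in% caseset$drugs$ingredient)) {
    warning("ingredient not present in case set: ", ingredient,
            call. = FALSE)
  }
  sel <- intersect(
    event_caseids(caseset, vocab$onj_pt_codes, vocab$onj_pt_names),
    ps_caseids(caseset, ingredient)
  )
  filter_caseset(caseset, sel)
}
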