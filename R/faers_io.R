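#' @name faers-dialect
#' @title The FAERS quarterly ASCII dialect
#'
#' @description
#' FAERS distributes quarterly extracts as "$"-delimited ASCII tables with a
#' one-line header. Six table kinds are supported, mirroring the quarterly
#' files: `DEMO` (one row per report version, demographics), `DRUG` (one row
#' per drug mention), `REAC` (reaction preferred terms), `INDI` (indication
#' preferred term per drug), `THER` (therapy start date per drug) and `OUTC`
#' (outcome codes). Column layouts:
#'
#' * `DEMO`: `primaryid`, `caseid`, `caseversion`, `event_dt`, `age`,
#'   `age_cod`, `sex`, `occp_cod`, `reporter_country`, `rept_yr`
#' * `DRUG`: `primaryid`, `drug_seq`, `role_cod`, `drugname`, `dose_amt`,
#'   `dose_unit`, `dose_freq`
#' * `REAC`: `primaryid`, `pt_cod`, `pt`
#' * `INDI`: `primaryid`, `indi_drug_seq`, `indi_pt`
#' * `THER`: `primaryid`, `dsg_drug_seq`, `start_dt`
#' * `OUTC`: `primaryid`, `outc_cod`
#'
#' Dates are partial-date strings (see [parse_partial_date()]); missing
#' values are empty fields.
NULL

# column layout, column types and row-level validators per dialect
faers_dialects <- function() {
  list(
    DEMO = list(
      columns = c("primaryid", "caseid", "caseversion", "event_dt", "age",
                  "age_cod", "sex", "occp_cod", "reporter_country",
                  "rept_yr"),
      integer = c("caseversion", "rept_yr"),
      numeric = "age",
      dates = "event_dt"
    ),
    DRUG = list(
      columns = c("primaryid", "drug_seq", "role_cod", "drugname",
                  "dose_amt", "dose_unit", "dose_freq"),
      integer = "drug_seq",
      numeric = "dose_amt",
      dates = character()
    ),
    REAC = list(
      columns = c("primaryid", "pt_cod", "pt"),
      integer = "pt_cod",
      numeric = character(),
      dates = character()
    ),
    INDI = list(
      columns = c("primaryid", "indi_drug_seq", "indi_pt"),
      integer = "indi_drug_seq",
      numeric = character(),
      dates = character()
    ),
    THER = list(
      columns = c("primaryid", "dsg_drug_seq", "start_dt"),
      integer = "dsg_drug_seq",
      numeric = character(),
      dates = "start_dt"
    ),
    OUTC = list(
      columns = c("primaryid", "outc_cod"),
      integer = character(),
      numeric = character(),
      dates = character()
    )
  )
}

role_codes    <- c("PS", "SS", "C", "I")
sex_codes     <- c("F", "M", "UNK")
occp_codes    <- c("MD", "PH", "OT", "CN", "LW", "UNK")
outcome_codes <- c("DE", "DS", "HO", "LT", "CA", "RI", "OT")

#' Read a FAERS-dialect delimited table
#'
#' Reads one quarterly-style ASCII table, validates each row, and separates
#' well-formed records from rejects. Malformed rows (wrong field count,
#' invalid partial dates, out-of-range codes, non-numeric counts) are never
#' silently dropped: they are returned with a reason so curation can report
#' them.
#'
#' @param path Path to the delimited text file. The first line must be a
#'   header matching the dialect's column layout.
#' @param dialect One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"INDI"`, `"THER"`,
#'   `"OUTC"`.
#' @param sep Field separator, by default the FAERS `"$"`.
#' @return A list with elements `records` (tibble of typed, accepted rows)
#'   and `rejects` (tibble with columns `line`, `reason`, `raw`). The
#'   accepted plus rejected row counts always equal the input data row
#'   count.
#' @seealso [write_faers_table()], [faers-dialect]
#' @export
read_faers_table <- function(path, dialect, sep = "$") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  spec <- faers_dialects()[[match.arg(dialect, names(faers_dialects()))]]

  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop("empty file (no header): ", path, call. = FALSE)
  }
  header <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  missing_cols <- setdiff(spec$columns, header)
  if (length(missing_cols) > 0L) {
    stop("header mismatch for dialect ", dialect, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  empty_records <- function() {
    rec <- tibble::as_tibble(setNames(
      rep(list(character(0)), length(spec$columns)), spec$columns))
    type_faers_columns(rec, spec)
  }
  if (n == 0L) {
    return(list(records = empty_records(),
                rejects = tibble::tibble(line = integer(0),
                                         reason = character(0),
                                         raw = character(0))))
  }

  parts <- strsplit(body, sep, fixed = TRUE)
  nf <- lengths(parts)
  # a trailing empty field is dropped by strsplit; pad it back
  short_one <- nf == length(header) - 1L
  parts[short_one] <- lapply(parts[short_one], function(p) c(p, ""))
  nf[short_one] <- length(header)

  reason <- rep(NA_character_, n)
  reason[nf != length(header)] <- "wrong field count"

  ok <- is.na(reason)
  mat <- matrix("", nrow = n, ncol = length(header))
  if (any(ok)) {
    mat[ok, ] <- do.call(rbind, parts[ok])
  }
  colnames(mat) <- header
  raw <- tibble::as_tibble(mat)[, spec$columns, drop = FALSE]
  raw[] <- lapply(raw, trimws)

  reason <- validate_faers_rows(raw, dialect, spec, reason, ok)

  keep <- is.na(reason)
  records <- type_faers_columns(raw[keep, , drop = FALSE], spec)
  rejects <- tibble::tibble(
    line = which(!keep) + 1L,  # 1-based file line, after the header
    reason = reason[!keep],
    raw = body[!keep]
  )
  list(records = records, rejects = rejects)
}

# row-level validation shared by all dialects; returns updated reason vector
validate_faers_rows <- function(raw, dialect, spec, reason, ok) {
  flag <- function(bad, why) {
    bad <- ok & is.na(reason) & bad
    reason[bad] <<- why
    invisible(NULL)
  }

  for (col in spec$dates) {
    p <- parse_partial_date(raw[[col]])
    flag(!p$valid, "invalid date")
  }
  for (col in spec$integer) {
    v <- raw[[col]]
    flag(nzchar(v) & is.na(suppressWarnings(as.integer(v))),
         paste0("non-integer ", col))
  }
  for (col in spec$numeric) {
    v <- raw[[col]]
    flag(nzchar(v) & is.na(suppressWarnings(as.numeric(v))),
         paste0("non-numeric ", col))
  }

  if (dialect == "DEMO") {
    flag(!nzchar(raw$primaryid), "missing primaryid")
    flag(nzchar(raw$sex) & !(raw$sex %in% sex_codes), "invalid sex code")
    cv <- suppressWarnings(as.integer(raw$caseversion))
    flag(!is.na(cv) & cv < 0L, "negative caseversion")
  }
  if (dialect == "DRUG") {
    flag(nzchar(raw$role_cod) & !(raw$role_cod %in% role_codes),
         "invalid role code")
    ds <- suppressWarnings(as.integer(raw$drug_seq))
    flag(!is.na(ds) & ds < 1L, "drug_seq < 1")
  }
  if (dialect == "REAC") {
    pc <- suppressWarnings(as.integer(raw$pt_cod))
    flag(!is.na(pc) & (pc < 10000000L | pc > 99999999L),
         "pt_cod not an 8-digit code")
  }
  if (dialect == "OUTC") {
    flag(nzchar(raw$outc_cod) & !(raw$outc_cod %in% outcome_codes),
         "invalid outcome code")
  }
  reason
}

type_faers_columns <- function(raw, spec) {
  out <- raw
  for (col in spec$integer) {
    out[[col]] <- suppressWarnings(as.integer(out[[col]]))
  }
  for (col in spec$numeric) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  # empty strings in character columns mean missing but are kept as ""
  tibble::as_tibble(out)
}

#' Write a FAERS-dialect delimited table
#'
#' Inverse of [read_faers_table()]: writes a header line and one
#' `sep`-joined line per record. `NA`s become empty fields, so a read/write
#' round trip is lossless for well-formed rows.
#'
#' @param records Tibble with the dialect's columns.
#' @param path Output file path.
#' @inheritParams read_faers_table
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(records, path, dialect, sep = "$") {
  spec <- faers_dialects()[[match.arg(dialect, names(faers_dialects()))]]
  missing_cols <- setdiff(spec$columns, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(records)[, spec$columns, drop = FALSE]
  df[] <- lapply(df, function(v) {
    v <- as.character(v)
    v[is.na(v)] <- ""
    v
  })
  lines <- c(paste(spec$columns, collapse = sep),
             do.call(paste, c(unname(df), list(sep = sep))))
  if (nrow(df) == 0L) lines <- lines[1L]
  writeLines(lines, path)
  invisible(path)
}

#' Write a full simulated dataset as FAERS-dialect files
#'
#' @param tables Named list with elements `demo`, `drug`, `reac`, `indi`,
#'   `ther`, `outc`, as produced by [generate_faers_dataset()].
#' @param dir Output directory, created if needed.
#' @inheritParams read_faers_table
#' @return Named character vector of the six file paths, invisibly.
#' @export
write_faers_dataset <- function(tables, dir, sep = "$") {
  stopifnot(all(c("demo", "drug", "reac", "indi", "ther", "outc") %in%
                  names(tables)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kinds <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
             indi = "INDI", ther = "THER", outc = "OUTC")
  paths <- vapply(names(kinds), function(k) {
    p <- file.path(dir, paste0(k, ".txt"))
    write_faers_table(tables[[k]], p, kinds[[k]], sep = sep)
    p
  }, character(1))
  invisible(paths)
}

#' Read a full dataset directory of FAERS-dialect files
#'
#' @param dir Directory containing `demo.txt`, `drug.txt`, `reac.txt`,
#'   `indi.txt`, `ther.txt`, `outc.txt`.
#' @inheritParams read_faers_table
#' @return A list with elements `tables` (named list of record tibbles) and
#'   `rejects` (named list of reject tibbles).
#' @export
read_faers_dataset <- function(dir, sep = "$") {
  kinds <- c(demo = "DEMO", drug = "DRUG", reac = "REAC",
             indi = "INDI", ther = "THER", outc = "OUTC")
  out <- lapply(names(kinds), function(k) {
    p <- file.path(dir, paste0(k, ".txt"))
    if (!file.exists(p)) {
      stop("missing table file for ", kinds[[k]], ": ", p, call. = FALSE)
    }
    read_faers_table(p, kinds[[k]], sep = sep)
  })
  names(out) <- names(kinds)
  list(tables = lapply(out, `[[`, "records"),
       rejects = lapply(out, `[[`, "rejects"))
}

#' Load a vocabulary fixture
#'
#' The package replaces licensed vocabulary services (RxNorm ingredient
#' normalisation, the full MedDRA hierarchy) with a small plain-text
#' fixture: a JSON document with three keys -- `ingredient_map` (verbatim
#' drug name to ingredient), `pt_to_hlt` (indication preferred term to
#' high-level term) and `onj_pt_codes` (the reaction PT codes that define
#' the ONJ event). The packaged default covers the eight antiresorptive
#' agents, their US brand names, and the indication terms used in the
#' stratified analyses.
#'
#' @param path Path to a vocabulary JSON file; the packaged default when
#'   omitted.
#' @return A list of class `onj_vocabulary` with elements `ingredient_map`
#'   (named character), `pt_to_hlt` (named character, names lower-cased) and
#'   `onj_pt_codes` (integer vector).
#' @details The ONJ event definition requires both the "osteonecrosis of the
#'   jaw" (10064658) and "exposed bone in jaw" (10071014) preferred-term
#'   codes; a fixture missing either is rejected.
#' @export
load_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vocabulary.json", package = "onjsignal")
  }
  if (!file.exists(path)) {
    stop("vocabulary file not found: ", path, call. = FALSE)
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("ingredient_map", "pt_to_hlt", "onj_pt_codes")) {
    if (is.null(doc[[key]])) {
      stop("vocabulary is missing key: ", key, call. = FALSE)
    }
  }
  codes <- as.integer(doc$onj_pt_codes)
  required <- c(10064658L, 10071014L)
  if (!all(required %in% codes)) {
    stop("vocabulary onj_pt_codes must include ",
         paste(setdiff(required, codes), collapse = ", "), call. = FALSE)
  }
  ing <- unlist(doc$ingredient_map)
  names(ing) <- toupper(trimws(names(ing)))
  hlt <- unlist(doc$pt_to_hlt)
  names(hlt) <- tolower(trimws(names(hlt)))
  nm <- doc$onj_pt_names
  if (is.null(nm)) {
    nm <- c("osteonecrosis of the jaw", "exposed bone in jaw")
  }
  structure(
    list(ingredient_map = ing, pt_to_hlt = hlt, onj_pt_codes = codes,
         onj_pt_names = tolower(trimws(as.character(nm)))),
    class = "onj_vocabulary"
  )
}

#' Normalise verbatim drug names to ingredients
#'
#' Verbatim names are upper-cased and stripped before lookup; names the
#' vocabulary cannot resolve pass through lower-cased and are tagged so
#' callers can report them.
#'
#' @param verbatim Character vector of verbatim drug names.
#' @param vocab An `onj_vocabulary`.
#' @return A tibble with columns `ingredient` and `mapped` (logical).
#' @export
normalize_drug_names <- function(verbatim, vocab) {
  key <- toupper(trimws(as.character(verbatim)))
  hit <- unname(vocab$ingredient_map[key])
  mapped <- !is.na(hit)
  out <- ifelse(mapped, hit, tolower(key))
  tibble::tibble(ingredient = unname(out), mapped = unname(mapped))
}

#' Resolve indication preferred terms to high-level terms
#'
#' @param pt Character vector of indication preferred terms (matched
#'   case-insensitively).
#' @param vocab An `onj_vocabulary`.
#' @return Character vector of HLT names, `NA` where unresolvable.
#' @export
pt_to_hlt <- function(pt, vocab) {
  key <- tolower(trimws(as.character(pt)))
  out <- unname(vocab$pt_to_hlt[key])
  out[!nzchar(key) | is.na(key)] <- NA_character_
  out
}
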