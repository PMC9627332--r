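#' Run the full ONJ signal pipeline
#'
#' Orchestrates the end-to-end analysis over a directory of
#' FAERS-dialect files: read and validate the six tables, deduplicate
#' and assemble the case set, compute the overall ("regardless of
#' indication") ROR per ingredient, the indication-HLT-stratified RORs,
#' the dose-frequency-indication-stratified RORs, the time-to-onset
#' summaries with Mann-Whitney comparisons, and the descriptive
#' breakdowns. All results are written as tab-separated files plus a
#' JSON run manifest. Every stage is a pure function of the inputs, so
#' reruns on the same inputs are bit-identical.
#'
#' @param data_dir Directory containing `demo.txt` .. `outc.txt` (see
#'   [read_faers_dataset()]).
#' @param out_dir Output directory, created if needed.
#' @param ingredients Ingredients to analyse; default: every ingredient
#'   the vocabulary maps to.
#' @param vocab An `onj_vocabulary`; the packaged default when omitted.
#' @param universe Comparator universe for stratified analyses, see
#'   [build_contingency()].
#' @param sep Field separator of the input files.
#' @return Invisibly, a list with the in-memory results (`caseset`,
#'   `overall`, `hlt`, `dose`, `onset`, `descriptive`, `manifest`).
#' @export
run_pipeline <- function(data_dir, out_dir, ingredients = NULL,
                         vocab = load_vocabulary(),
                         universe = "stratum", sep = "$") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- read_faers_dataset(data_dir, sep = sep)
  caseset <- assemble_cases(ds$tables, vocab)

  if (is.null(ingredients)) {
    known <- unique(unname(vocab$ingredient_map))
    ingredients <- intersect(known, unique(caseset$drugs$ingredient))
  }

  overall <- ror_overall(caseset, ingredients, vocab)
  write_tsv_file(overall, file.path(out_dir, "ror_overall.tsv"))

  hlts <- sort(unique(stats::na.omit(
    caseset$drugs$indication_hlt[caseset$drugs$role_cod == "PS"])))
  hlt <- dplyr::bind_rows(lapply(ingredients, function(ing) {
    stratified_ror(caseset, ing, vocab$onj_pt_codes, vocab$onj_pt_names,
                   strata = lapply(hlts, stratum_hlt),
                   universe = universe)
  }))
  write_tsv_file(hlt, file.path(out_dir, "ror_hlt.tsv"))

  dose <- dplyr::bind_rows(lapply(ingredients, function(ing) {
    d <- caseset$drugs
    ps <- d[d$role_cod == "PS" & d$ingredient == ing &
              !is.na(d$dose_label) & !is.na(d$dose_freq) &
              !is.na(d$indication_category), , drop = FALSE]
    keys <- unique(ps[, c("dose_label", "dose_freq",
                          "indication_category")])
    if (nrow(keys) == 0L) return(NULL)
    strata <- lapply(seq_len(nrow(keys)), function(i) {
      stratum_dose(keys$dose_label[i], keys$dose_freq[i],
                   keys$indication_category[i])
    })
    stratified_ror(caseset, ing, vocab$onj_pt_codes, vocab$onj_pt_names,
                   strata = strata, universe = universe)
  }))
  write_tsv_file(dose, file.path(out_dir, "ror_dose.tsv"))

  onset_rows <- list()
  mw_rows <- list()
  for (ing in ingredients) {
    sel <- suppressWarnings(select_onj_cases(caseset, vocab, ing))
    if (nrow(sel$cases) == 0L) next
    cmp <- compare_onset_by_group(sel, ing)
    onset_rows[[ing]] <- cmp$summary
    if (!is.null(cmp$test)) {
      mw_rows[[ing]] <- tibble::tibble(
        ingredient = ing, u_statistic = cmp$test$u_statistic,
        p_value = cmp$test$p_value, method = cmp$test$method,
        n1 = cmp$test$n1, n2 = cmp$test$n2
      )
    }
  }
  onset_tab <- dplyr::bind_rows(onset_rows)
  write_tsv_file(onset_tab, file.path(out_dir, "onset_summary.tsv"))
  mw_tab <- dplyr::bind_rows(mw_rows)
  write_tsv_file(mw_tab, file.path(out_dir, "onset_tests.tsv"))

  desc_rows <- list()
  year_rows <- list()
  for (ing in ingredients) {
    sel <- suppressWarnings(select_onj_cases(caseset, vocab, ing))
    if (nrow(sel$cases) == 0L) next
    vars <- c("sex", "continent", "reporter_group", "indication_group",
              "outcome")
    desc_rows[[ing]] <- dplyr::bind_rows(
      lapply(vars, function(v) {
        tibble::tibble(ingredient = ing, summarize_categorical(sel, v))
      })
    )
    yc <- yearly_counts(sel)
    if (nrow(yc) > 0L) {
      year_rows[[ing]] <- tibble::tibble(ingredient = ing, yc)
    }
  }
  descriptive <- dplyr::bind_rows(desc_rows)
  write_tsv_file(descriptive, file.path(out_dir, "descriptive.tsv"))
  yearly <- dplyr::bind_rows(year_rows)
  write_tsv_file(yearly, file.path(out_dir, "yearly_counts.tsv"))

  manifest <- list(
    inputs = lapply(ds$tables, nrow),
    rejects = lapply(ds$rejects, nrow),
    assembly_log = as.list(caseset$log),
    ingredients = ingredients,
    universe = universe,
    outputs = c("ror_overall.tsv", "ror_hlt.tsv", "ror_dose.tsv",
                "onset_summary.tsv", "onset_tests.tsv",
                "descriptive.tsv", "yearly_counts.tsv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(caseset = caseset, overall = overall, hlt = hlt,
                 dose = dose, onset = onset_tab, mw = mw_tab,
                 descriptive = descriptive, yearly = yearly,
                 manifest = manifest))
}

# deterministic TSV writer: fixed column order, no quoting surprises
write_tsv_file <- function(df, path) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- if (is.null(df)) tibble::tibble(empty = character(0)) else df
  }
  utils::write.table(as.data.frame(df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Simulate a dataset to disk
#'
#' Convenience wrapper: build (or accept) a scenario configuration,
#' generate the dataset, and write the six FAERS-dialect files plus a
#' `ground_truth.json`.
#'
#' @param out_dir Output directory.
#' @param cfg An `onj_simconfig`; [scenario_paperlike()] with the given
#'   seed when omitted.
#' @param seed Seed used when `cfg` is omitted.
#' @return Invisibly, the generation result of
#'   [generate_faers_dataset()].
#' @export
simulate_to_dir <- function(out_dir, cfg = NULL, seed = 20210930) {
  if (is.null(cfg)) {
    cfg <- scenario_paperlike(seed = seed)
  }
  gen <- generate_faers_dataset(cfg)
  write_faers_dataset(gen$tables, out_dir)
  jsonlite::write_json(
    list(signals = gen$ground_truth$signals,
         realized = gen$ground_truth$realized),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(gen)
}
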