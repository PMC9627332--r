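onj_pts <- c(10064658L, 10071014L)

four_cell_tables <- function() {
  make_tables(
    demo = dplyr::bind_rows(
      demo_row("P1", "C1"), demo_row("P2", "C2"),
      demo_row("P3", "C3"), demo_row("P4", "C4")
    ),
    drug = dplyr::bind_rows(
      drug_row("P1", "ZOMETA", "PS"),
      drug_row("P2", "FOSAMAX", "PS"),
      drug_row("P3", "ZOMETA", "PS"),
      drug_row("P4", "FOSAMAX", "PS")
    ),
    reac = dplyr::bind_rows(
      reac_row("P1"),
      reac_row("P2"),
      reac_row("P3", 10028813L, "nausea"),
      reac_row("P4", 10028813L, "nausea")
    )
  )
}

test_that("one hand-built case per cell lands in each cell", {
  cs <- assemble_cases(four_cell_tables(), test_vocab())
  tab <- build_contingency(cs, "zoledronic acid", onj_pts)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 1))
  expect_equal(tab$n, nrow(cs$cases))
})

test_that("contingency cells match a brute-force per-report oracle", {
  cfg <- scenario_paperlike(n_reports = 500, seed = 12)
  gen <- generate_faers_dataset(cfg)
  vocab <- test_vocab()
  cs <- assemble_cases(gen$tables, vocab)
  for (ing in c("zoledronic acid", "denosumab", "metformin")) {
    tab <- build_contingency(cs, ing, onj_pts, vocab$onj_pt_names)
    bf <- brute_force_cells(cs, ing, onj_pts, vocab$onj_pt_names)
    expect_equal(list(a = tab$a, b = tab$b, c = tab$c, d = tab$d), bf,
                 info = ing)
    expect_equal(tab$a + tab$b + tab$c + tab$d, nrow(cs$cases))
  }
})

test_that("an HLT stratum universe is the reports in that HLT", {
  cfg <- scenario_paperlike(n_reports = 800, seed = 13)
  gen <- generate_faers_dataset(cfg)
  vocab <- test_vocab()
  cs <- assemble_cases(gen$tables, vocab)
  s <- stratum_hlt("metabolic bone disorders")
  tab <- build_contingency(cs, "zoledronic acid", onj_pts,
                           vocab$onj_pt_names, stratum = s)
  bf <- brute_force_cells(cs, "zoledronic acid", onj_pts,
                          vocab$onj_pt_names, stratum = s)
  expect_equal(list(a = tab$a, b = tab$b, c = tab$c, d = tab$d), bf)

  ps <- cs$drugs[cs$drugs$role_cod == "PS", ]
  n_in_hlt <- length(unique(
    ps$caseid[!is.na(ps$indication_hlt) &
                ps$indication_hlt == "metabolic bone disorders"]))
  expect_equal(tab$n, n_in_hlt)
})

test_that("the ROR formula and Woolf interval match hand arithmetic", {
  r <- compute_ror(list(a = 10, b = 90, c = 100, d = 9900))
  # ln(11) = 2.3978953, se = sqrt(0.1212121) = 0.3481553,
  # bounds exp(2.3978953 -/+ 1.96 * 0.3481553)
  expect_equal(r$ror, 11.0)
  expect_equal(r$ci_low, exp(log(11) - 1.96 * sqrt(4 / 33)),
               tolerance = 1e-12)
  expect_equal(r$ci_low, 5.5595, tolerance = 1e-4)
  expect_equal(r$ci_high, 21.7645, tolerance = 1e-4)
  expect_true(r$is_signal)

  sym <- compute_ror(list(a = 5, b = 5, c = 5, d = 5))
  expect_equal(sym$ror, 1.0)
  expect_false(sym$is_signal)
})

test_that("zero cells are incalculable unless the correction is opted in", {
  r0 <- compute_ror(list(a = 0, b = 10, c = 10, d = 100))
  expect_true(r0$incalculable)
  expect_true(is.na(r0$ror))
  expect_false(r0$is_signal)

  rh <- compute_ror(list(a = 0, b = 10, c = 10, d = 100),
                    correction = "haldane")
  expect_false(rh$incalculable)
  expect_equal(rh$ror, (0.5 * 100.5) / (10.5 * 10.5))
})

test_that("the alternative interval form shrinks the standard error", {
  cells <- list(a = 10, b = 90, c = 100, d = 9900)
  woolf <- compute_ror(cells)
  alt <- compute_ror(cells, ci_form = "plus_one")
  expect_equal(alt$ror, woolf$ror)
  expect_gt(alt$ci_low, woolf$ci_low)  # smaller se, tighter interval
})

test_that("signal criteria require a >= 3 and a strict lower bound", {
  expect_true(apply_signal_criteria(3, 1.001))
  expect_false(apply_signal_criteria(2, 50))
  expect_false(apply_signal_criteria(100, 1.0))
  expect_false(apply_signal_criteria(3, NA))
})

test_that("ROR is invariant to cell scaling while the CI narrows", {
  base <- compute_ror(list(a = 4, b = 40, c = 36, d = 920))
  for (k in c(2, 5, 10)) {
    sc <- compute_ror(list(a = 4 * k, b = 40 * k, c = 36 * k,
                           d = 920 * k))
    expect_equal(sc$ror, base$ror)
    expect_gt(sc$ci_low, base$ci_low)
    expect_lt(sc$ci_high, base$ci_high)
  }
})

test_that("a stratum-specific multiplier separates stratified RORs", {
  drugs <- tibble::tibble(
    ingredient = c("zoledronic acid", "metformin"),
    prob = c(0.3, 0.7),
    indications = list(
      tibble::tibble(pt = c("metastases to bone", "osteoporosis"),
                     prob = c(0.5, 0.5)),
      tibble::tibble(pt = c("metastases to bone", "osteoporosis"),
                     prob = c(0.5, 0.5))
    ),
    regimens = list(NULL, NULL)
  )
  events <- tibble::tibble(pt_cod = 10064658L,
                           pt = "osteonecrosis of the jaw", prob = 0.02)
  signals <- tibble::tibble(ingredient = "zoledronic acid",
                            pt_cod = 10064658L,
                            indication_group = "CancerRelated",
                            theta = 20)
  cfg <- simulation_config(n_reports = 8000, drugs = drugs,
                           events = events, signals = signals, seed = 5)
  gen <- generate_faers_dataset(cfg)
  vocab <- test_vocab()
  cs <- assemble_cases(gen$tables, vocab)
  res <- stratified_ror(
    cs, "zoledronic acid", onj_pts, vocab$onj_pt_names,
    strata = list(stratum_hlt("metastases to specified sites"),
                  stratum_hlt("metabolic bone disorders"))
  )
  expect_equal(nrow(res), 2L)
  expect_gt(res$ror[1], 5 * res$ror[2])
})

test_that("empty strata report rather than abort, duplicates error", {
  cs <- assemble_cases(four_cell_tables(), test_vocab())
  res <- stratified_ror(
    cs, "zoledronic acid", onj_pts,
    strata = list(stratum_hlt("no such term"))
  )
  expect_equal(res$note, "no reports in stratum")
  expect_equal(res$n_reports, 0)

  expect_error(
    stratified_ror(cs, "zoledronic acid", onj_pts,
                   strata = list(stratum_hlt("x"), stratum_hlt("x"))),
    "overlapping"
  )
  expect_error(
    stratified_ror(cs, "zoledronic acid", onj_pts,
                   strata = list(stratum_hlt("x"),
                                 stratum_dose("4 mg", "Q4W",
                                              "Metastasis"))),
    "same kind"
  )
})

test_that("signals rank by ROR, then report count, then name", {
  res <- dplyr::bind_rows(
    tibble::tibble(ingredient = "z", ror = 6.4, n_reports = 10),
    tibble::tibble(ingredient = "pamidronate", ror = 494.8,
                   n_reports = 300),
    tibble::tibble(ingredient = "zoledronic acid", ror = 431.9,
                   n_reports = 7000),
    tibble::tibble(ingredient = "b", ror = 6.4, n_reports = 50),
    tibble::tibble(ingredient = "a", ror = 6.4, n_reports = 50)
  )
  ranked <- rank_signals(res)
  expect_equal(ranked$ingredient,
               c("pamidronate", "zoledronic acid", "a", "b", "z"))
  expect_equal(nrow(rank_signals(res[0, ])), 0L)
})

test_that("the dose-frequency-indication stratum routes reports", {
  cfg <- scenario_paperlike(n_reports = 3000, seed = 21)
  gen <- generate_faers_dataset(cfg)
  vocab <- test_vocab()
  cs <- assemble_cases(gen$tables, vocab)
  s <- stratum_dose("4 mg", "Q4W", "Metastasis")
  tab <- build_contingency(cs, "zoledronic acid", onj_pts,
                           vocab$onj_pt_names, stratum = s)
  bf <- brute_force_cells(cs, "zoledronic acid", onj_pts,
                          vocab$onj_pt_names, stratum = s)
  expect_equal(list(a = tab$a, b = tab$b, c = tab$c, d = tab$d), bf)
  expect_gt(tab$a + tab$c, 0)  # exposed reports exist in the stratum
})
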