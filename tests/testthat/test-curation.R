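test_that("deduplication keeps the highest case version", {
  demo <- dplyr::bind_rows(
    demo_row("C1.1", "C1", 1),
    demo_row("C1.2", "C1", 2),
    demo_row("C2.1", "C2", 1)
  )
  out <- deduplicate_cases(demo)
  expect_equal(sort(out$primaryid), c("C1.2", "C2.1"))
  # idempotent, and identity on a single record
  expect_equal(deduplicate_cases(out), out)
  one <- demo_row("C9.1", "C9")
  expect_equal(deduplicate_cases(one), one)
})

test_that("version ties break by report year, then largest primaryid", {
  demo <- dplyr::bind_rows(
    demo_row("A.1", "C1", 2, rept_yr = 2015),
    demo_row("B.1", "C1", 2, rept_yr = 2018),
    demo_row("C.1", "C2", 1, rept_yr = 2016),
    demo_row("D.1", "C2", 1, rept_yr = 2016)
  )
  out <- deduplicate_cases(demo)
  expect_equal(out$primaryid[out$caseid == "C1"], "B.1")
  expect_equal(out$primaryid[out$caseid == "C2"], "D.1")
})

test_that("deduplicated size equals the number of distinct case ids", {
  set.seed(11)
  n <- 1000
  caseid <- sprintf("C%04d", sample.int(900, n, replace = TRUE))
  demo <- demo_row(paste0(caseid, ".", seq_len(n)), caseid,
                   caseversion = sample.int(3, n, replace = TRUE))
  out <- deduplicate_cases(demo)
  expect_equal(nrow(out), length(unique(caseid)))
})

test_that("assembly joins drugs, reactions and indications onto cases", {
  tables <- make_tables(
    demo = demo_row("P1", "C1"),
    drug = dplyr::bind_rows(
      drug_row("P1", "FOSAMAX", "PS", 1),
      drug_row("P1", "ZOMETA", "C", 2)
    ),
    reac = reac_row("P1"),
    indi = tibble::tibble(primaryid = "P1", indi_drug_seq = 1L,
                          indi_pt = "osteoporosis"),
    ther = tibble::tibble(primaryid = "P1", dsg_drug_seq = 1L,
                          start_dt = "20150101")
  )
  cs <- assemble_cases(tables, test_vocab())
  expect_equal(nrow(cs$cases), 1L)
  expect_equal(nrow(cs$drugs), 2L)
  ps <- cs$drugs[cs$drugs$role_cod == "PS", ]
  expect_equal(ps$ingredient, "alendronate")
  expect_equal(ps$indication_pt, "osteoporosis")
  expect_equal(ps$indication_hlt, "metabolic bone disorders")
  expect_equal(ps$indication_group, "OsteoporosisRelated")
  expect_equal(ps$therapy_start, "20150101")
})

test_that("orphan child rows are logged, not fatal", {
  tables <- make_tables(
    demo = demo_row("P1", "C1"),
    reac = dplyr::bind_rows(reac_row("P1"), reac_row("GHOST"))
  )
  cs <- assemble_cases(tables, test_vocab())
  expect_equal(unname(cs$log["orphan_reac"]), 1)
  expect_equal(nrow(cs$reactions), 1L)
  expect_equal(nrow(cs$cases), 1L)
})

test_that("indication groups merge per the configured term lists", {
  expect_equal(
    merge_indication_groups(c("osteoporosis postmenopause",
                              "metastases to bone", "asthma",
                              NA, "")),
    c("OsteoporosisRelated", "CancerRelated", "Other",
      "Missing", "Missing")
  )
  # osteopetrosis is deliberately on the osteoporosis-related list
  expect_equal(merge_indication_groups("Osteopetrosis"),
               "OsteoporosisRelated")
})

test_that("dose-analysis categories keep prophylaxis separate", {
  expect_equal(
    merge_dose_indication_categories(
      c("breast cancer metastatic", "neoplasm malignant",
        "osteoporosis prophylaxis", "osteoporosis", "asthma")),
    c("Metastasis", "Malignancy", "Prophylaxis", "Osteoporosis", NA)
  )
})

test_that("ONJ case selection requires the event PT and the PS role", {
  tables <- make_tables(
    demo = dplyr::bind_rows(
      demo_row("P1", "C1"), demo_row("P2", "C2"),
      demo_row("P3", "C3"), demo_row("P4", "C4")
    ),
    drug = dplyr::bind_rows(
      drug_row("P1", "ZOMETA", "PS"),      # PS + ONJ -> selected
      drug_row("P2", "ZOMETA", "SS"),      # SS only -> not selected
      drug_row("P3", "ZOMETA", "PS"),      # PS, both PTs -> once
      drug_row("P4", "ZOMETA", "PS")       # PS, no ONJ -> not selected
    ),
    reac = dplyr::bind_rows(
      reac_row("P1"),
      reac_row("P2"),
      reac_row("P3", 10064658L),
      reac_row("P3", 10071014L, "exposed bone in jaw"),
      reac_row("P4", 10028813L, "nausea")
    )
  )
  vocab <- test_vocab()
  cs <- assemble_cases(tables, vocab)
  sel <- select_onj_cases(cs, vocab, "zoledronic acid")
  expect_setequal(sel$cases$caseid, c("C1", "C3"))
  # C3 appears once despite carrying both event PTs
  expect_equal(sum(sel$cases$caseid == "C3"), 1L)
})

test_that("selection by name works when the reaction row has no code", {
  tables <- make_tables(
    demo = demo_row("P1", "C1"),
    drug = drug_row("P1", "XGEVA", "PS"),
    reac = tibble::tibble(primaryid = "P1", pt_cod = NA_integer_,
                          pt = "Osteonecrosis of the jaw")
  )
  vocab <- test_vocab()
  cs <- assemble_cases(tables, vocab)
  sel <- select_onj_cases(cs, vocab, "denosumab")
  expect_equal(nrow(sel$cases), 1L)
})

test_that("an unknown ingredient yields an empty result with a warning", {
  tables <- make_tables(
    demo = demo_row("P1", "C1"),
    drug = drug_row("P1", "ZOMETA", "PS"),
    reac = reac_row("P1")
  )
  vocab <- test_vocab()
  cs <- assemble_cases(tables, vocab)
  expect_warning(sel <- select_onj_cases(cs, vocab, "unobtainium"),
                 "not present")
  expect_equal(nrow(sel$cases), 0L)
})

test_that("per-ingredient PS case sets are disjoint and bounded", {
  cfg <- scenario_paperlike(n_reports = 1200, seed = 3)
  gen <- generate_faers_dataset(cfg)
  vocab <- test_vocab()
  cs <- assemble_cases(gen$tables, vocab)
  ings <- c("zoledronic acid", "denosumab", "alendronate", "pamidronate")
  sets <- lapply(ings, function(ing) {
    suppressWarnings(select_onj_cases(cs, vocab, ing)$cases$caseid)
  })
  for (i in seq_along(sets)) {
    expect_true(all(sets[[i]] %in% cs$cases$caseid))
    for (j in seq_along(sets)) {
      if (i < j) expect_length(intersect(sets[[i]], sets[[j]]), 0L)
    }
  }
  # one primary suspect per report: PS counts sum to at most the total
  ps <- cs$drugs[cs$drugs$role_cod == "PS", ]
  expect_lte(length(unique(ps$caseid)), nrow(cs$cases))
})
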