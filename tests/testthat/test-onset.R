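test_that("onset days are calendar differences at day precision only", {
  expect_equal(compute_onset_days("20160101", "20161231"), 365L)
  expect_equal(compute_onset_days("20150101", "20151231"), 364L)
  expect_true(is.na(compute_onset_days("201601", "20161231")))
  expect_true(is.na(compute_onset_days("20160101", "2016")))
  # event before therapy start is a data error, excluded
  expect_true(is.na(compute_onset_days("20161231", "20160101")))
  expect_equal(compute_onset_days("20160101", "20160101"), 0L)
})

test_that("onset summaries use interpolated quartiles", {
  rec <- tibble::tibble(ingredient = "x",
                        indication_group = "OsteoporosisRelated",
                        onset_days = c(1, 2, 3, 4, 5))
  s <- summarize_onset(rec)
  expect_equal(c(s$q1, s$median, s$q3), c(2, 3, 4))

  rec2 <- tibble::tibble(ingredient = "x", indication_group = "g",
                         onset_days = c(10, 20))
  expect_equal(summarize_onset(rec2)$median, 15)
})

test_that("onset summaries match an independent sort-and-index oracle", {
  set.seed(99)
  x <- round(rlnorm(1000, log(500), 0.9))
  # type-7 quantile by hand: h = (n-1)p, interpolate adjacent order stats
  oracle_q <- function(v, p) {
    v <- sort(v)
    h <- (length(v) - 1) * p
    lo <- floor(h) + 1
    v[lo] + (h - floor(h)) * (v[min(lo + 1, length(v))] - v[lo])
  }
  rec <- tibble::tibble(ingredient = "x", indication_group = "g",
                        onset_days = x)
  s <- summarize_onset(rec)
  expect_equal(s$median, oracle_q(x, 0.5))
  expect_equal(s$q1, oracle_q(x, 0.25))
  expect_equal(s$q3, oracle_q(x, 0.75))
  expect_true(s$q1 <= s$median && s$median <= s$q3)
})

test_that("onset extraction excludes partial dates and uses the earliest start", {
  tables <- make_tables(
    demo = dplyr::bind_rows(
      demo_row("P1", "C1", event_dt = "20200110"),
      demo_row("P2", "C2", event_dt = "202001")     # month precision
    ),
    drug = dplyr::bind_rows(
      drug_row("P1", "ZOMETA", "PS", 1),
      drug_row("P1", "ZOMETA", "PS", 2),
      drug_row("P2", "ZOMETA", "PS", 1)
    ),
    ther = tibble::tibble(
      primaryid = c("P1", "P1", "P2"),
      dsg_drug_seq = c(1L, 2L, 1L),
      start_dt = c("20200101", "20190101", "20190601")
    ),
    reac = dplyr::bind_rows(reac_row("P1"), reac_row("P2"))
  )
  cs <- assemble_cases(tables, test_vocab())
  rec <- onset_records(cs, "zoledronic acid")
  expect_equal(nrow(rec$records), 1L)
  # earliest complete start 2019-01-01 to 2020-01-10 = 374 days
  expect_equal(rec$records$onset_days, 374L)
  expect_equal(unname(rec$excluded["no_day_precision"]), 1)
})

test_that("the exact Mann-Whitney p matches full enumeration", {
  x <- c(1, 2); y <- c(3, 4)
  r <- mann_whitney(x, y)
  expect_equal(r$u_statistic, 0)
  expect_equal(r$method, "exact")

  # oracle: enumerate every assignment of the pooled values to group 1
  pooled <- c(x, y)
  splits <- utils::combn(4, 2)
  u_of <- function(idx) {
    rk <- rank(pooled)
    sum(rk[idx]) - length(idx) * (length(idx) + 1) / 2
  }
  u_obs <- u_of(1:2)
  u_all <- apply(splits, 2, u_of)
  mu <- length(x) * length(y) / 2
  p_oracle <- mean(abs(u_all - mu) >= abs(u_obs - mu))
  expect_equal(p_oracle, 1 / 3)
  expect_equal(r$p_value, p_oracle, tolerance = 1e-12)
})

test_that("U statistics of the two orderings sum to n1 * n2", {
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(mann_whitney(x, y)$u_statistic +
                   mann_whitney(y, x)$u_statistic, n1 * n2)
  }
})

test_that("identical samples give p = 1", {
  x <- 1:20
  r <- mann_whitney(x, x)
  expect_equal(r$p_value, 1, tolerance = 0.02)

  const <- mann_whitney(c(5, 5, 5), c(5, 5))
  expect_equal(const$p_value, 1)
  expect_equal(const$method, "degenerate")
})

test_that("exact and normal-approximation p agree on tie-free n = 15", {
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15, 0.3)
    r <- mann_whitney(x, y)  # n1*n2 = 225 <= 400, tie-free: exact route
    expect_equal(r$method, "exact")
    p_norm <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(r$p_value - p_norm), 0.02)
  }
})

test_that("the p-value is invariant under strictly monotone transforms", {
  set.seed(8)
  x <- rlnorm(12); y <- rlnorm(15, 0.5)
  p0 <- mann_whitney(x, y)$p_value
  expect_equal(mann_whitney(log(x), log(y))$p_value, p0)
  expect_equal(mann_whitney(x^3, y^3)$p_value, p0)
})

test_that("group comparison returns summaries and a test per drug", {
  cfg <- scenario_paperlike(n_reports = 4000, seed = 31)
  gen <- generate_faers_dataset(cfg)
  vocab <- test_vocab()
  cs <- assemble_cases(gen$tables, vocab)
  sel <- select_onj_cases(cs, vocab, "zoledronic acid")
  cmp <- compare_onset_by_group(sel, "zoledronic acid")
  expect_true(all(c("n", "median", "q1", "q3") %in% names(cmp$summary)))
  expect_true(all(cmp$summary$q1 <= cmp$summary$median))
  expect_true(all(cmp$summary$median <= cmp$summary$q3))
  if (!is.null(cmp$test)) {
    expect_gte(cmp$test$p_value, 0)
    expect_lte(cmp$test$p_value, 1)
  }
})
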