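test_that("age bands are left-closed at 18/45/65 and missing goes to UNK", {
  demo <- tibble::tibble(
    primaryid = as.character(1:6), caseid = as.character(1:6),
    fda_dt = "20200101",
    age = c("17.9", "18", "44.9", "45", "65", NA), age_cod = "YR",
    sex = c("F", "F", "M", "M", "F", "F"))
  reac <- tibble::tibble(primaryid = as.character(1:6), pt = "31000001")
  drug <- tibble::tibble(primaryid = as.character(1:6), drugname = "x",
                         role_cod = "PS")
  cases <- assemble_cases(demo, drug, reac)
  s <- summarize_characteristics(cases)
  got <- stats::setNames(s$age$n, s$age$value)
  expect_equal(unname(got[c("<18", "18-44", "45-64", ">=65", "UNK")]),
               c(1, 2, 1, 1, 1))
  expect_equal(sum(s$age$n), nrow(cases$cases))
  expect_equal(sum(s$age$pct), 100, tolerance = 0.1)
  expect_equal(s$sex$pct[s$sex$value == "F"], 66.67, tolerance = 0.01)
})

test_that("onset days subtract first PS start from event date", {
  demo <- tibble::tibble(
    primaryid = c("1", "2", "3"), caseid = c("1", "2", "3"),
    fda_dt = "20200301",
    event_dt = c("20200107", "20200101", "20200101"))
  drug <- tibble::tibble(
    primaryid = c("1", "2", "3"), drug_seq = "1",
    drugname = "enoxaparin", role_cod = "PS")
  ther <- tibble::tibble(
    primaryid = c("1", "2", "3"), dsg_drug_seq = "1",
    start_dt = c("20200101", "20200101", "20200115"))
  reac <- tibble::tibble(primaryid = c("1", "2", "3"), pt = "31000001")
  cases <- assemble_cases(demo, drug, reac, ther = ther,
                          synonym_map = tiny_synonyms())
  d <- onset_days(cases, "enoxaparin")
  expect_equal(unname(d[c("1", "2")]), c(6, 0)) # 0 is a legal onset
  expect_true(is.na(d["3"]))                    # event before start
})

test_that("onset quartiles agree with a sort-and-interpolate oracle", {
  # independent inline implementation of linear quantile interpolation
  q_oracle <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(99)
  for (i in 1:200) {
    x <- round(rexp(sample(3:40, 1), 1 / 20))
    got <- stats::quantile(x, c(.25, .5, .75), type = 7, names = FALSE)
    expect_equal(got, c(q_oracle(x, .25), q_oracle(x, .5), q_oracle(x, .75)),
                 tolerance = 1e-12)
  }
})

test_that("annual counts bucket by receipt year and sum to cohort size", {
  demo <- tibble::tibble(
    primaryid = as.character(1:5), caseid = as.character(1:5),
    fda_dt = c("20200101", "20200601", "20201231", "20210101", "0101"))
  reac <- tibble::tibble(primaryid = as.character(1:5), pt = "31000001")
  drug <- tibble::tibble(primaryid = as.character(1:5), drugname = "x",
                         role_cod = "PS")
  cases <- assemble_cases(demo, drug, reac)
  ac <- annual_counts(cases)
  expect_equal(ac$n[ac$year == "2020"], 3)
  expect_equal(ac$n[ac$year == "2021"], 1)
  expect_equal(ac$n[ac$year == "UNK"], 1)
  expect_equal(sum(ac$n), nrow(cases$cases))
  expect_equal(nrow(annual_counts(subset_cases(cases, character(0)))), 0)
})

test_that("top terms rank by frequency with k-invariant percentages", {
  cases <- assemble_tiny()
  cnt <- tabulate_events(cases, c("enoxaparin", "dalteparin"),
                         dict = tiny_dictionary())
  t2 <- top_terms(cnt, k = 2)
  t_all <- top_terms(cnt, k = 1000)
  expect_equal(nrow(t2), 2)
  expect_true(all(diff(t_all$a) <= 0))
  # percentages identical regardless of k
  expect_equal(t2$pct, t_all$pct[match(t2$term, t_all$term)])
  # k larger than number of terms returns all terms
  expect_equal(nrow(t_all), nrow(cnt$pt))
  expect_error(top_terms(cnt, k = 0), "positive")
})
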