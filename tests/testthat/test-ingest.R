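test_that("the quarterly-table parser preserves rows, missings and skips", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_bundle(dir)
  demo <- parse_faers_table(paths$demo, "demo")
  expect_equal(nrow(demo), 3)
  expect_true(is.na(demo$age[demo$primaryid == "102"]))
  drug <- parse_faers_table(paths$drug, "drug")
  expect_equal(drug$role_cod[drug$primaryid == "101"], "PS")

  # malformed row (wrong field count) skipped with counter
  bad <- file.path(dir, "REACBAD.txt")
  writeLines(c("primaryid$pt", "7$100$extra$junk", "8$200"), bad)
  expect_message(tab <- parse_faers_table(bad, "reac"), "skipped 1")
  expect_equal(nrow(tab), 1)
  expect_equal(attr(tab, "skipped"), 1)

  # missing required column is a hard error naming it
  nohdr <- file.path(dir, "DEMOBAD.txt")
  writeLines(c("primaryid$fda_dt", "1$20200101"), nohdr)
  expect_error(parse_faers_table(nohdr, "demo"), "caseid")
})

test_that("case versions deduplicate to latest date, ties to largest primaryid", {
  demo <- tibble::tibble(
    primaryid = c("70", "71", "80", "81", "90"),
    caseid = c("7", "7", "8", "8", "9"),
    fda_dt = c("20200101", "20210101", "20190301", "20190301", "20220101"))
  dd <- deduplicate_cases(demo)
  expect_setequal(dd$demo$primaryid, c("71", "81", "90"))
  expect_equal(dd$n_removed, 2)
  expect_setequal(dd$removed$primaryid, c("70", "80"))

  # brute-force oracle: per caseid, sort by (fda_dt, primaryid) and take last
  oracle <- vapply(split(demo, demo$caseid), function(g) {
    g <- g[order(as.numeric(g$fda_dt), as.numeric(g$primaryid)), ]
    g$primaryid[nrow(g)]
  }, "")
  expect_setequal(dd$demo$primaryid, unname(oracle))

  # idempotent; no duplicates -> identity
  expect_equal(deduplicate_cases(dd$demo)$n_removed, 0)
  expect_equal(nrow(dd$demo), length(unique(demo$caseid)))
})

test_that("missing caseid becomes a singleton case with a warning", {
  demo <- tibble::tibble(primaryid = c("1", "2"),
                         caseid = c(NA, "5"),
                         fda_dt = c("20200101", "20200101"))
  expect_warning(dd <- deduplicate_cases(demo), "singleton")
  expect_equal(nrow(dd$demo), 2)
})

test_that("assembly dedups reactions, drops empty reports and orphans", {
  cases <- assemble_tiny()
  # report 101 listed PT 31000001 twice -> one event
  r101 <- cases$reactions$pt_code[cases$reactions$primaryid == "101"]
  expect_setequal(r101, c(31000001L, 31000002L))
  expect_equal(nrow(cases$cases), 3)

  # a report with no reactions is excluded
  demo <- tibble::tibble(primaryid = c("1", "2"), caseid = c("1", "2"),
                         fda_dt = "20200101")
  reac <- tibble::tibble(primaryid = "1", pt = "31000001")
  drug <- tibble::tibble(primaryid = c("1", "2", "99"), drugname = "x",
                         role_cod = "PS")
  out <- assemble_cases(demo, drug, reac)
  expect_equal(out$cases$primaryid, "1")
  expect_equal(out$counters$no_reaction, 1)
  expect_equal(out$counters$orphan_drug, 1)
})

test_that("age harmonization converts units and rejects negatives", {
  demo <- tibble::tibble(
    primaryid = as.character(1:5), caseid = as.character(1:5),
    fda_dt = "20200101",
    age = c("60", "18", "730", "-4", "abc"),
    age_cod = c("YR", "MON", "DY", "YR", "YR"))
  reac <- tibble::tibble(primaryid = as.character(1:5), pt = "31000001")
  drug <- tibble::tibble(primaryid = as.character(1:5), drugname = "x",
                         role_cod = "PS")
  out <- assemble_cases(demo, drug, reac)
  expect_equal(out$cases$age_years[1], 60)
  expect_equal(out$cases$age_years[2], 1.5)
  expect_equal(out$cases$age_years[3], 730 / 365.25)
  expect_true(all(is.na(out$cases$age_years[4:5])))
})

test_that("primary-suspect target filtering excludes concomitant-only reports", {
  cases <- assemble_tiny()
  out <- filter_target_reports(cases, c("enoxaparin", "dalteparin"))
  # 101: LOVENOX PS -> in; 102: enoxaparin only as C -> out; 103: PS -> in
  expect_setequal(out$cases$primaryid, c("101", "103"))
  # idempotent
  again <- filter_target_reports(out, c("enoxaparin", "dalteparin"))
  expect_identical(again$cases, out$cases)
  expect_error(filter_target_reports(cases, character(0)), "non-empty")
})
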