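test_that("the generator is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_cases = 1500, seed = 5,
                          planted_signals = tibble::tibble(
                            pt_code = 11000050L, rr = 10))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_faers(cfg, dir = d1)
  generate_faers(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("duplicate rate zero emits exactly one DEMO row per case", {
  cfg <- synthetic_config(n_cases = 800, duplicate_rate = 0, seed = 3)
  b <- generate_faers(cfg)
  expect_equal(nrow(b$tables$demo), 800)
  expect_equal(nrow(b$manifest$duplicates), 0)
})

test_that("config validation rejects bad probabilities and foreign PTs", {
  expect_error(synthetic_config(target_drug_share = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_config(
    planted_signals = tibble::tibble(pt_code = 11000050L, rr = -1)), "> 0")
  expect_error(synthetic_config(
    n_pts = 10,
    planted_signals = tibble::tibble(pt_code = 11000050L, rr = 2)),
    "vocabulary")
})

test_that("manifest totals equal pipeline tabulation (event conservation)", {
  cfg <- synthetic_config(n_cases = 4000, seed = 21,
                          planted_signals = tibble::tibble(
                            pt_code = 11000080L, rr = 8))
  b <- generate_faers(cfg)
  cases <- assemble_synthetic(b)
  cnt <- tabulate_events(cases, b$vocab$target_ingredients, b$vocab$dict)
  expect_equal(cnt$N, b$manifest$totals$n_events)
  expect_equal(nrow(cases$cases), b$manifest$totals$n_reports)
  man <- b$manifest$cases
  expect_equal(sum(man$n_reactions), cnt$N)
  # per-case event counts match the manifest
  per_case <- table(cases$reactions$primaryid)
  expect_equal(unname(as.integer(per_case[man$primaryid])),
               man$n_reactions)
})

test_that("deduplication removes exactly the planted duplicate versions", {
  cfg <- synthetic_config(n_cases = 3000, duplicate_rate = 0.1, seed = 9)
  b <- generate_faers(cfg)
  dd <- deduplicate_cases(b$tables$demo)
  expect_setequal(dd$removed$primaryid, b$manifest$duplicates$primaryid)
  expect_setequal(dd$demo$primaryid, b$manifest$cases$primaryid)
})

test_that("cohort retrieval recovers exactly the manifest pregnancy labels", {
  cfg <- synthetic_config(n_cases = 6000, pregnancy_fraction = 0.08,
                          paternal_fraction = 0.01, seed = 13)
  b <- generate_faers(cfg)
  cases <- assemble_synthetic(b)
  co <- build_cohort(cases, b$vocab$dict, b$vocab$lists)
  man <- b$manifest$cases
  expect_setequal(
    co$cohort_ids,
    man$primaryid[man$pregnancy_label %in% c("definitive", "other")])
  lab <- stats::setNames(co$labels$label, co$labels$primaryid)
  expect_setequal(names(lab[lab == "definitive"]),
                  man$primaryid[man$pregnancy_label == "definitive"])
  expect_setequal(names(lab[lab == "excluded"]),
                  man$primaryid[man$pregnancy_label == "excluded"])
})

test_that("a strongly planted signal is recovered with a consistent EBGM", {
  cfg <- synthetic_config(n_cases = 60000, seed = 31,
                          planted_signals = tibble::tibble(
                            pt_code = 11000200L, rr = 20))
  b <- generate_faers(cfg)
  cases <- assemble_synthetic(b)
  cnt <- tabulate_events(cases, b$vocab$target_ingredients, b$vocab$dict)
  st <- signal_table(cnt, "pt")
  rec <- evaluate_recovery(st, b$manifest)
  expect_true(rec$planted$detected)
  expect_gt(rec$planted$ebgm, 20 / 2)
  expect_lt(rec$planted$ebgm, 20 * 2)
  expect_true(rec$planted$covered)
  expect_lte(rec$false_signal_rate, 0.01)
})

test_that("recovery with no planted signals reports an empty list", {
  cfg <- synthetic_config(n_cases = 1000, seed = 2)
  b <- generate_faers(cfg)
  cases <- assemble_synthetic(b)
  st <- signal_table(tabulate_events(cases, b$vocab$target_ingredients,
                                     b$vocab$dict), "pt")
  rec <- evaluate_recovery(st, b$manifest)
  expect_equal(nrow(rec$planted), 0)
})

test_that("the analytic expected count tracks the realized count", {
  cfg <- synthetic_config(n_cases = 60000, seed = 17,
                          planted_signals = tibble::tibble(
                            pt_code = 11000150L, rr = 15))
  exp_a <- expected_signal_counts(cfg)$expected_a
  b <- generate_faers(cfg)
  expect_gt(b$manifest$planted$a_realized, exp_a * 0.5)
  expect_lt(b$manifest$planted$a_realized, exp_a * 2)
})
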