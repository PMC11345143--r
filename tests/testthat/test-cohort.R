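# A small hand-built case set exercising every classification branch.
cohort_fixture <- function() {
  demo <- tibble::tibble(
    primaryid = as.character(1:7), caseid = as.character(1:7),
    fda_dt = "20200101",
    age = c("30", "30", "30", "5", "30", NA, "30"),
    age_cod = "YR",
    sex = c("F", "F", "M", "F", "F", "F", "F"))
  # 1: definitive PT; 2: transplacental route only (+ SMQ state);
  # 3: paternal PT (+ definitive PT: paternal wins); 4: pediatric w/ SMQ;
  # 5: SMQ event state only; 6: indication evidence only; 7: no evidence
  reac <- tibble::tibble(
    primaryid = c("1", "2", "3", "3", "4", "5", "6", "7"),
    pt = c("10071408", "12000001", "10050425", "10071408", "12000001",
           "12000001", "31000001", "31000002"))
  indi <- tibble::tibble(primaryid = "6", indi_pt = "12100001")
  drug <- tibble::tibble(
    primaryid = as.character(1:7), drugname = "enoxaparin", role_cod = "PS",
    route = c("Subcutaneous", "Transplacental", rep("Subcutaneous", 5)))
  assemble_cases(demo, drug, reac, indi, synonym_map = tiny_synonyms())
}

test_that("SMQ flags fire on reactions and indications separately", {
  cases <- cohort_fixture()
  dict <- tiny_dictionary()
  lists <- tiny_lists()
  ev <- flag_smq_events(cases, dict, lists)
  ind <- flag_smq_indications(cases, dict, lists)
  ids <- cases$cases$primaryid
  expect_setequal(ids[ev], c("1", "2", "3", "4", "5"))
  expect_setequal(ids[ind], c("6"))
  # a PT that is an event-SMQ member appearing only as indication: no flag
  expect_false(ind[ids == "5"])
  expect_error(flag_smq_events(cases, dict,
                               pregnancy_term_lists(event_smqs = 20999999L)),
               "20999999")
})

test_that("classification partitions definitive/other/excluded/non-pregnancy", {
  cases <- cohort_fixture()
  lab <- classify_pregnancy(cases, tiny_dictionary(), tiny_lists(),
                            pediatric_age_cutoff = 12)
  got <- stats::setNames(lab$label, lab$primaryid)
  expect_equal(unname(got[c("1", "2")]), c("definitive", "definitive"))
  expect_equal(unname(got["3"]), "excluded")   # paternal beats definitive
  expect_equal(unname(got["4"]), "excluded")   # pediatric
  expect_equal(unname(got[c("5", "6")]), c("other", "other"))
  expect_equal(unname(got["7"]), "non_pregnancy")
  expect_match(lab$reasons[lab$primaryid == "3"], "paternal")
  expect_match(lab$reasons[lab$primaryid == "2"], "transplacental_route")
  expect_match(lab$reasons[lab$primaryid == "4"], "pediatric")

  # exhaustive and mutually exclusive partition
  expect_true(all(lab$label %in%
                    c("definitive", "other", "excluded", "non_pregnancy")))
  expect_equal(nrow(lab), nrow(cases$cases))
  # pure function: rerun identical
  expect_identical(lab, classify_pregnancy(cases, tiny_dictionary(),
                                           tiny_lists(),
                                           pediatric_age_cutoff = 12))
})

test_that("male reports are annotated by default and excluded on request", {
  cases <- cohort_fixture()
  lab <- classify_pregnancy(cases, tiny_dictionary(), tiny_lists())
  expect_match(lab$reasons[lab$primaryid == "3"], "ineligible_demographics")
  lab2 <- classify_pregnancy(cases, tiny_dictionary(), tiny_lists(),
                             exclude_male = TRUE)
  expect_equal(lab2$label[lab2$primaryid == "3"], "excluded")
})

test_that("cohort audit counts are consistent and double hits count once", {
  cases <- cohort_fixture()
  co <- build_cohort(cases, tiny_dictionary(), tiny_lists())
  a <- co$audit
  expect_equal(a[["final"]], a[["definitive"]] + a[["other"]])
  expect_lte(a[["union"]], a[["smq_event_hits"]] + a[["smq_indication_hits"]])
  expect_equal(length(co$cohort_ids), a[["final"]])
  expect_equal(anyDuplicated(co$cohort_ids), 0)

  # a case hit by both event and indication routes appears once
  demo <- tibble::tibble(primaryid = "1", caseid = "1", fda_dt = "20200101",
                         sex = "F", age = "30", age_cod = "YR")
  reac <- tibble::tibble(primaryid = "1", pt = "12000001")
  indi <- tibble::tibble(primaryid = "1", indi_pt = "12100001")
  drug <- tibble::tibble(primaryid = "1", drugname = "enoxaparin",
                         role_cod = "PS", route = "Subcutaneous")
  both <- assemble_cases(demo, drug, reac, indi,
                         synonym_map = tiny_synonyms())
  co2 <- build_cohort(both, tiny_dictionary(), tiny_lists())
  expect_equal(co2$audit[["smq_event_hits"]], 1)
  expect_equal(co2$audit[["smq_indication_hits"]], 1)
  expect_equal(co2$audit[["union"]], 1)
  expect_equal(co2$audit[["final"]], 1)
})

test_that("an all-excluded input yields an empty cohort", {
  demo <- tibble::tibble(primaryid = "1", caseid = "1", fda_dt = "20200101",
                         sex = "M", age = "40", age_cod = "YR")
  reac <- tibble::tibble(primaryid = "1", pt = "10050425")
  drug <- tibble::tibble(primaryid = "1", drugname = "enoxaparin",
                         role_cod = "PS", route = "Oral")
  cases <- assemble_cases(demo, drug, reac, synonym_map = tiny_synonyms())
  co <- build_cohort(cases, tiny_dictionary(), tiny_lists())
  expect_equal(co$audit[["final"]], 0)
  expect_length(co$cohort_ids, 0)
})
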