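# Fixtures built in code: a tiny term dictionary, a tiny raw table
# bundle, and shortcuts for synthetic bundles.

# 12 PTs / 2 SOCs / 2 SMQs, using the published pregnancy codes plus filler
tiny_dictionary <- function() {
  pt <- tibble::tibble(
    pt_code = c(10071408L, 10071407L, 10050425L, 10073513L,
                12000001L, 12100001L,
                31000001L, 31000002L, 31000003L, 31000004L, 31000005L,
                31000006L),
    pt_name = c("maternal exposure during pregnancy",
                "maternal exposure during delivery",
                "paternal drugs affecting the fetus",
                "exposure during pregnancy",
                "pregnancy state filler", "pregnancy indication filler",
                paste("filler term", 1:6)),
    soc_name = c(rep("pregnancy, puerperium and perinatal conditions", 6),
                 rep("investigations", 6))
  )
  smq <- tibble::tibble(
    smq_code = c(rep(20000077L, 4), rep(20000186L, 2)),
    pt_code = c(10071408L, 10073513L, 12000001L, 10050425L,
                10071408L, 12100001L)
  )
  term_dictionary(pt, smq)
}

tiny_lists <- function() {
  pregnancy_term_lists(
    definitive_pts = c(10071408L, 10071407L, 10073513L),
    paternal_pts = 10050425L,
    event_smqs = 20000077L,
    indication_smqs = 20000186L
  )
}

tiny_synonyms <- function() {
  drug_synonym_map(
    tibble::tibble(raw_name = c("enoxaparin", "lovenox", "dalteparin"),
                   ingredient = c("enoxaparin", "enoxaparin", "dalteparin")),
    target_ingredients = c("enoxaparin", "dalteparin")
  )
}

# write a minimal "$"-delimited bundle to dir and return the paths
write_tiny_bundle <- function(dir) {
  w <- function(name, lines) {
    path <- file.path(dir, name)
    writeLines(lines, path)
    path
  }
  list(
    demo = w("DEMO.txt", c(
      "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$occr_country$reporter_country",
      "101$1$20200115$20200110$65$YR$F$MD$US$US",
      "102$2$20210301$$$$M$PH$$FR",
      "103$3$20220401$20220330$30$YR$F$CN$BR$BR")),
    drug = w("DRUG.txt", c(
      "primaryid$drug_seq$drugname$role_cod$route",
      "101$1$LOVENOX$PS$Subcutaneous",
      "102$1$enoxaparin$C$Oral",
      "102$2$BACKGROUND DRUG 01$PS$Oral",
      "103$1$enoxaparin$PS$TRANSPLACENTAL")),
    reac = w("REAC.txt", c(
      "primaryid$pt",
      "101$31000001", "101$31000002", "101$31000001",
      "102$31000003",
      "103$10071408", "103$31000004")),
    indi = w("INDI.txt", c(
      "primaryid$indi_pt",
      "103$12100001")),
    ther = w("THER.txt", c(
      "primaryid$dsg_drug_seq$start_dt",
      "101$1$20200104",
      "103$1$20220330")),
    outc = w("OUTC.txt", c(
      "primaryid$outc_cod",
      "101$HO", "103$CA"))
  )
}

assemble_tiny <- function(dir = withr::local_tempdir()) {
  paths <- write_tiny_bundle(dir)
  demo <- parse_faers_table(paths$demo, "demo")
  drug <- parse_faers_table(paths$drug, "drug")
  reac <- parse_faers_table(paths$reac, "reac")
  indi <- parse_faers_table(paths$indi, "indi")
  ther <- parse_faers_table(paths$ther, "ther")
  outc <- parse_faers_table(paths$outc, "outc")
  assemble_cases(deduplicate_cases(demo)$demo, drug, reac, indi, ther, outc,
                 synonym_map = tiny_synonyms())
}

# random valid 2x2 tables for property tests
random_tables <- function(n, seed = 42, nmax = 1e6) {
  set.seed(seed)
  tibble::tibble(
    a = as.numeric(sample(1:80, n, replace = TRUE)),
    b = as.numeric(sample(1:5000, n, replace = TRUE)),
    c = as.numeric(sample(1:5000, n, replace = TRUE)),
    d = as.numeric(sample(1000:nmax, n, replace = TRUE))
  )
}
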