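# Synthetic spontaneous-report generator: emits FAERS-dialect bundles
# with known ground truth (planted (drug, PT) relative risks, pregnancy
# subcohorts, duplicate case versions) so the whole pipeline is testable
# without any database download.

soc_names <- c(
  "investigations",
  "vascular disorders",
  "blood and lymphatic system disorders",
  "gastrointestinal disorders",
  "nervous system disorders",
  "injury, poisoning and procedural complications",
  "product issues",
  "skin and subcutaneous tissue disorders"
)

definitive_pt_names <- c(
  "10071407" = "maternal exposure during delivery",
  "10071409" = "foetal exposure during delivery",
  "10071406" = "maternal exposure before pregnancy",
  "10071408" = "maternal exposure during pregnancy",
  "10071404" = "foetal exposure during pregnancy",
  "10073513" = "exposure during pregnancy",
  "10071415" = "maternal exposure timing unspecified",
  "10071405" = "foetal exposure timing unspecified",
  "10026923" = "maternal drugs affecting foetus",
  "10064998" = "drug exposure before pregnancy"
)

paternal_pt_names <- c(
  "10050425" = "paternal drugs affecting the fetus",
  "10071403" = "exposure via father",
  "10080091" = "paternal exposure during pregnancy",
  "10080092" = "paternal exposure timing unspecified",
  "10080093" = "paternal exposure before pregnancy",
  "10084938" = "maternal exposure via partner during pregnancy"
)

target_synonym_table <- function() {
  targets <- c("enoxaparin", "nadroparin", "dalteparin", "tinzaparin",
               "bemiparin", "reviparin", "parnaparin")
  brands <- c(lovenox = "enoxaparin", clexane = "enoxaparin",
              fragmin = "dalteparin", fraxiparine = "nadroparin",
              innohep = "tinzaparin", hibor = "bemiparin",
              clivarin = "reviparin", fluxum = "parnaparin",
              "low molecular weight heparin" = "enoxaparin")
  tibble::tibble(
    raw_name = c(targets, names(brands)),
    ingredient = c(targets, unname(brands))
  )
}

#' Synthetic term dictionary, pregnancy code lists and drug synonyms
#'
#' Builds a deterministic fixture vocabulary: `n_pts` generic adverse
#' event PTs spread over eight SOCs, the maternal/foetal and paternal
#' exposure PTs with their published 8-digit codes, invented pregnancy
#' state and pregnancy indication terms, the six pregnancy SMQ code sets
#' (paternal terms are members so that paternal reports are retrieved and
#' then excluded), and a low-molecular-weight-heparin synonym map. All
#' content other than the literal codes is synthetic filler; no licensed
#' terminology ships with the package.
#'
#' @param n_pts number of generic adverse event PTs.
#' @return list with `dict` ([term_dictionary()]), `lists`
#'   ([pregnancy_term_lists()]), `synonyms` ([drug_synonym_map()]) and
#'   `target_ingredients`.
#' @export
synthetic_dictionary <- function(n_pts = 200) {
  base_codes <- 11000000L + seq_len(n_pts)
  base <- tibble::tibble(
    pt_code = base_codes,
    pt_name = sprintf("synthetic ae term %03d", seq_len(n_pts)),
    soc_name = rep_len(soc_names, n_pts)
  )
  preg_soc <- "pregnancy, puerperium and perinatal conditions"
  definitive <- tibble::tibble(
    pt_code = as.integer(names(definitive_pt_names)),
    pt_name = unname(definitive_pt_names), soc_name = preg_soc)
  paternal <- tibble::tibble(
    pt_code = as.integer(names(paternal_pt_names)),
    pt_name = unname(paternal_pt_names), soc_name = preg_soc)
  states <- tibble::tibble(
    pt_code = 12000000L + 1:12,
    pt_name = sprintf("synthetic pregnancy state %02d", 1:12),
    soc_name = preg_soc)
  indic <- tibble::tibble(
    pt_code = 12100000L + 1:6,
    pt_name = sprintf("synthetic pregnancy indication %02d", 1:6),
    soc_name = preg_soc)
  pt <- dplyr::bind_rows(base, definitive, paternal, states, indic)

  smq <- dplyr::bind_rows(
    tibble::tibble(smq_code = 20000077L,
                   pt_code = c(definitive$pt_code, states$pt_code[1:4])),
    tibble::tibble(smq_code = 20000186L,
                   pt_code = c(states$pt_code[5:6], indic$pt_code[1:2],
                               10071408L)),
    tibble::tibble(smq_code = 20000190L,
                   pt_code = c(states$pt_code[7:8], indic$pt_code[3:4])),
    tibble::tibble(smq_code = 20000191L,
                   pt_code = c(states$pt_code[9:10], paternal$pt_code)),
    tibble::tibble(smq_code = 20000192L, pt_code = states$pt_code[11:12]),
    tibble::tibble(smq_code = 20000193L, pt_code = indic$pt_code[5:6])
  )
  syn <- target_synonym_table()
  targets <- unique(syn$ingredient)
  list(dict = term_dictionary(pt, smq),
       lists = pregnancy_term_lists(),
       synonyms = drug_synonym_map(syn, targets),
       target_ingredients = targets)
}

zipf_weights <- function(n, s) {
  w <- seq_len(n)^(-s)
  w / sum(w)
}

#' Synthetic bundle configuration
#'
#' Study conditions of the generator. PT marginal frequencies follow a
#' Zipf law (exponent `zipf_s`) over `n_pts` generic adverse event
#' terms, mimicking the heavy-tailed term distribution of spontaneous
#' report databases; each report draws `max(1, Poisson(reactions_lambda))`
#' reaction PTs (draws are per-event selections, duplicates collapse).
#' For reports whose primary-suspect drug is the target class, the
#' selection odds of planted PTs are multiplied by their relative risk
#' and renormalized.
#'
#' @param n_cases number of cases (deduplicated reports).
#' @param n_pts generic PT vocabulary size.
#' @param n_background_drugs number of non-target drugs.
#' @param zipf_s Zipf exponent of the PT marginals.
#' @param reactions_lambda Poisson mean of reaction draws per report.
#' @param target_drug_share probability a case's PS drug is the target.
#' @param planted_signals data frame `pt_code`, `rr` of planted relative
#'   risks (codes must be in the generic vocabulary), or `NULL`.
#' @param pregnancy_fraction probability a case carries pregnancy SMQ
#'   evidence.
#' @param definitive_fraction share of pregnancy cases given definitive
#'   evidence (a maternal/foetal exposure PT or a transplacental route).
#' @param paternal_fraction probability a non-pregnancy case carries a
#'   paternal-exposure PT (retrieved by SMQ, then excluded).
#' @param duplicate_rate probability a case emits an extra earlier
#'   version (same caseid, older receipt date, smaller primaryid).
#' @param seed integer seed fixing the full output byte-for-byte.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 20000, n_pts = 200,
                             n_background_drugs = 20, zipf_s = 1.2,
                             reactions_lambda = 2.5,
                             target_drug_share = 0.02,
                             planted_signals = NULL,
                             pregnancy_fraction = 0.05,
                             definitive_fraction = 0.5,
                             paternal_fraction = 0.005,
                             duplicate_rate = 0.03,
                             seed = 1L) {
  probs <- c(target_drug_share, pregnancy_fraction, definitive_fraction,
             paternal_fraction, duplicate_rate)
  if (any(probs < 0 | probs > 1)) abort_fs("probabilities must be in [0, 1]")
  if (!is.null(planted_signals)) {
    planted_signals <- tibble::as_tibble(planted_signals)
    stopifnot(all(c("pt_code", "rr") %in% names(planted_signals)))
    if (any(planted_signals$rr <= 0)) abort_fs("relative risks must be > 0")
    if (nrow(planted_signals) > n_pts ||
        !all(planted_signals$pt_code %in% (11000000L + seq_len(n_pts)))) {
      abort_fs("vocabulary smaller than planted-signal list ",
               "(planted codes must be generic vocabulary PTs)")
    }
  }
  structure(list(n_cases = as.integer(n_cases), n_pts = as.integer(n_pts),
                 n_background_drugs = as.integer(n_background_drugs),
                 zipf_s = zipf_s, reactions_lambda = reactions_lambda,
                 target_drug_share = target_drug_share,
                 planted_signals = planted_signals,
                 pregnancy_fraction = pregnancy_fraction,
                 definitive_fraction = definitive_fraction,
                 paternal_fraction = paternal_fraction,
                 duplicate_rate = duplicate_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# per-draw selection probabilities for target-drug cases
target_weights <- function(config) {
  w <- zipf_weights(config$n_pts, config$zipf_s)
  if (!is.null(config$planted_signals)) {
    idx <- config$planted_signals$pt_code - 11000000L
    w[idx] <- w[idx] * config$planted_signals$rr
    w <- w / sum(w)
  }
  w
}

#' Analytic expected target event counts for planted signals
#'
#' Power-calculation oracle: for each planted signal, the expected number
#' of target-drug reports containing the PT, computed from the generator
#' model in closed form. With `K ~ max(1, Poisson(lambda))` draws and
#' per-draw probability `p`, `P(PT in report) = 1 - e^(-lambda*p) +
#' p*e^(-lambda)` and `E[a] = n_cases * target_drug_share * P`.
#'
#' @param config a [synthetic_config()] with planted signals.
#' @return tibble `pt_code`, `rr`, `p_draw`, `expected_a`.
#' @export
expected_signal_counts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$planted_signals)) {
    return(tibble::tibble(pt_code = integer(), rr = numeric(),
                          p_draw = numeric(), expected_a = numeric()))
  }
  w <- target_weights(config)
  idx <- config$planted_signals$pt_code - 11000000L
  p <- w[idx]
  lam <- config$reactions_lambda
  p_in <- 1 - exp(-lam * p) + p * exp(-lam)
  tibble::tibble(pt_code = config$planted_signals$pt_code,
                 rr = config$planted_signals$rr,
                 p_draw = p,
                 expected_a = config$n_cases * config$target_drug_share * p_in)
}

sample_dates <- function(n, years = 2004:2023, weights = seq_along(years)) {
  y <- sample(years, n, replace = TRUE, prob = weights)
  m <- sample(1:12, n, replace = TRUE)
  d <- sample(1:28, n, replace = TRUE)
  sprintf("%04d%02d%02d", y, m, d)
}

shift_date8 <- function(x, days) {
  format(as.Date(x, format = "%Y%m%d") + days, "%Y%m%d")
}

#' Generate a synthetic FAERS-dialect bundle with ground truth
#'
#' Draws `n_cases` reports under the configuration's study conditions and
#' returns the six tables (DEMO, DRUG, REAC, INDI, THER, OUTC) plus a
#' manifest of true labels: per-case pregnancy status, duplicate
#' versions, per-planted-signal realized counts and bundle totals. With
#' `dir` given, the tables are also written as "$"-delimited files
#' (`DEMO.txt`, ...) and the manifest as `manifest.json`. The same seed
#' reproduces the bundle byte-for-byte.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory.
#' @param vocab dictionary bundle from [synthetic_dictionary()]; must use
#'   the same `n_pts` as the config.
#' @return list with `tables` (named list of tibbles), `manifest`,
#'   `vocab` and `dir`.
#' @export
generate_faers <- function(config, dir = NULL,
                           vocab = synthetic_dictionary(config$n_pts)) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- config$n_cases
  caseid <- 1000000L + seq_len(n)
  primaryid <- as.character(caseid * 100L + 2L)
  caseid_ch <- as.character(caseid)

  fda_dt <- sample_dates(n)
  target <- stats::runif(n) < config$target_drug_share
  preg <- stats::runif(n) < config$pregnancy_fraction
  paternal <- !preg & stats::runif(n) < config$paternal_fraction

  # demographics; pregnancy reports are adult and female-dominated so the
  # manifest labels equal the default cohort (no demographic exclusions)
  sex <- sample(c("F", "M", NA), n, replace = TRUE, prob = c(.45, .40, .15))
  sex[preg] <- sample(c("F", NA), sum(preg), replace = TRUE, prob = c(.9, .1))
  age <- ifelse(stats::runif(n) < 0.7,
                pmax(0, round(stats::rnorm(n, 58, 19))), NA)
  age[preg] <- round(stats::runif(sum(preg), 18, 44))
  occp <- sample(c("CN", "MD", "PH", "OT", NA), n, replace = TRUE,
                 prob = c(.25, .25, .25, .15, .10))
  country <- sample(c("US", "FR", "GB", "BR", "DE", NA), n, replace = TRUE,
                    prob = c(.4, .15, .1, .1, .1, .15))

  # event/therapy dates: onset measured from therapy start, median a few
  # days after start
  onset <- round(stats::rexp(n, 1 / 10))
  event_dt <- shift_date8(fda_dt, -sample(0:90, n, replace = TRUE))
  start_dt <- shift_date8(event_dt, -onset)
  event_dt[stats::runif(n) < 0.2] <- NA
  start_dt[stats::runif(n) < 0.2] <- NA

  # primary-suspect drug
  syn <- target_synonym_table()
  variants <- c(syn$raw_name, toupper(syn$raw_name))
  drugname <- sprintf("BACKGROUND DRUG %02d",
                      sample(config$n_background_drugs, n, replace = TRUE))
  drugname[target] <- sample(variants, sum(target), replace = TRUE)
  route <- sample(c("Subcutaneous", "Oral", "Unknown", NA), n, replace = TRUE,
                  prob = c(.35, .25, .25, .15))

  # reactions: per-draw PT selection, planted relative risks boost the
  # odds for target cases; duplicates within a report collapse
  k <- pmax(1L, stats::rpois(n, config$reactions_lambda))
  w_bg <- zipf_weights(config$n_pts, config$zipf_s)
  w_tg <- target_weights(config)
  draws <- integer(sum(k))
  case_of_draw <- rep(seq_len(n), k)
  tg_draw <- target[case_of_draw]
  draws[tg_draw] <- sample.int(config$n_pts, sum(tg_draw), replace = TRUE,
                               prob = w_tg)
  draws[!tg_draw] <- sample.int(config$n_pts, sum(!tg_draw), replace = TRUE,
                                prob = w_bg)
  reac <- dplyr::distinct(tibble::tibble(
    primaryid = primaryid[case_of_draw],
    pt = as.character(11000000L + draws)))

  # pregnancy evidence: SMQ-member state PTs in REAC and/or INDI
  states <- 12000000L + 1:12
  indic_members <- 12100000L + 1:6
  ev_type <- character(n)
  ev_type[preg] <- sample(c("event", "indication", "both"), sum(preg),
                          replace = TRUE, prob = c(.55, .25, .20))
  definitive <- preg & stats::runif(n) < config$definitive_fraction
  def_by_route <- definitive & stats::runif(n) < 0.5
  def_by_pt <- definitive & !def_by_route
  route[def_by_route] <- "TRANSPLACENTAL"

  add_ev <- preg & ev_type %in% c("event", "both")
  add_ind <- preg & ev_type %in% c("indication", "both")
  reac_extra <- tibble::tibble(
    primaryid = primaryid[add_ev],
    pt = as.character(sample(states, sum(add_ev), replace = TRUE)))
  reac_def <- tibble::tibble(
    primaryid = primaryid[def_by_pt],
    pt = as.character(sample(as.integer(names(definitive_pt_names)),
                             sum(def_by_pt), replace = TRUE)))
  reac_pat <- tibble::tibble(
    primaryid = primaryid[paternal],
    pt = as.character(sample(as.integer(names(paternal_pt_names)),
                             sum(paternal), replace = TRUE)))
  reac <- dplyr::distinct(dplyr::bind_rows(reac, reac_extra, reac_def,
                                           reac_pat))

  # indications: background noise + pregnancy indication evidence
  has_indi <- stats::runif(n) < 0.3
  indi <- dplyr::bind_rows(
    tibble::tibble(
      primaryid = primaryid[has_indi],
      indi_pt = as.character(11000000L +
        sample.int(config$n_pts, sum(has_indi), replace = TRUE, prob = w_bg))),
    tibble::tibble(
      primaryid = primaryid[add_ind],
      indi_pt = as.character(sample(indic_members, sum(add_ind),
                                    replace = TRUE)))
  )

  # outcomes
  n_outc <- sample(0:2, n, replace = TRUE, prob = c(.3, .5, .2))
  outc_case <- rep(seq_len(n), n_outc)
  outc <- dplyr::distinct(tibble::tibble(
    primaryid = primaryid[outc_case],
    outc_cod = sample(c("OT", "HO", "DE", "LT", "DS", "CA", "RI"),
                      length(outc_case), replace = TRUE,
                      prob = c(.40, .30, .12, .08, .04, .03, .03))))

  demo <- tibble::tibble(
    primaryid = primaryid, caseid = caseid_ch, fda_dt = fda_dt,
    event_dt = event_dt,
    age = ifelse(is.na(age), NA, as.character(age)),
    age_cod = ifelse(is.na(age), NA, "YR"),
    sex = sex, occp_cod = occp, occr_country = country,
    reporter_country = country)
  drug <- tibble::tibble(
    primaryid = primaryid, drug_seq = "1", drugname = drugname,
    role_cod = "PS", route = route)
  ther <- tibble::tibble(primaryid = primaryid, dsg_drug_seq = "1",
                         start_dt = start_dt)

  # duplicate earlier case versions: same caseid, older fda_dt, smaller
  # primaryid; their child rows become orphans after deduplication
  dup <- stats::runif(n) < config$duplicate_rate
  dup_primaryid <- as.character(caseid[dup] * 100L + 1L)
  if (any(dup)) {
    demo_dup <- demo[dup, ]
    demo_dup$primaryid <- dup_primaryid
    demo_dup$fda_dt <- shift_date8(demo_dup$fda_dt, -200)
    demo <- dplyr::bind_rows(demo, demo_dup)
    drug_dup <- drug[dup, ]
    drug_dup$primaryid <- dup_primaryid
    drug <- dplyr::bind_rows(drug, drug_dup)
    reac_dup <- tibble::tibble(
      primaryid = dup_primaryid,
      pt = as.character(11000000L + draws[match(which(dup), case_of_draw)]))
    reac <- dplyr::bind_rows(reac, reac_dup)
  }

  preg_label <- rep("none", n)
  preg_label[preg] <- "other"
  preg_label[definitive] <- "definitive"
  preg_label[paternal] <- "excluded"

  n_reac <- table(factor(reac$primaryid[reac$primaryid %in% primaryid],
                         levels = primaryid))
  manifest <- list(
    seed = config$seed,
    cases = tibble::tibble(
      primaryid = primaryid, caseid = caseid_ch, target = target,
      pregnancy_label = preg_label, has_duplicate = dup,
      year = substr(fda_dt, 1, 4),
      n_reactions = as.integer(n_reac)),
    duplicates = tibble::tibble(
      primaryid = dup_primaryid, caseid = caseid_ch[dup],
      duplicate_of = primaryid[dup]),
    totals = list(n_reports = n,
                  n_events = sum(as.integer(n_reac)),
                  n_demo_rows = nrow(demo))
  )
  if (!is.null(config$planted_signals)) {
    exp_tab <- expected_signal_counts(config)
    cur <- reac[reac$primaryid %in% primaryid, ]
    cur$pt_code <- as.integer(cur$pt)
    cur$is_target <- cur$primaryid %in% primaryid[target]
    realized <- cur |>
      dplyr::filter(.data$pt_code %in% exp_tab$pt_code) |>
      dplyr::group_by(pt_code = .data$pt_code) |>
      dplyr::summarise(a_realized = sum(.data$is_target),
                       term_total_realized = dplyr::n(), .groups = "drop")
    manifest$planted <- dplyr::left_join(exp_tab, realized, by = "pt_code")
    manifest$planted$a_realized[is.na(manifest$planted$a_realized)] <- 0L
    manifest$planted$term_total_realized[
      is.na(manifest$planted$term_total_realized)] <- 0L
  }

  tables <- list(demo = demo, drug = drug, reac = reac, indi = indi,
                 ther = ther, outc = outc)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(tables)) {
      utils::write.table(tables[[nm]],
                         file.path(dir, paste0(toupper(nm), ".txt")),
                         sep = "$", quote = FALSE, row.names = FALSE,
                         na = "", fileEncoding = "UTF-8")
    }
    json <- jsonlite::toJSON(list(seed = manifest$seed,
                                  totals = manifest$totals),
                             auto_unbox = TRUE, pretty = TRUE)
    writeLines(json, file.path(dir, "manifest.json"))
    utils::write.table(manifest$cases, file.path(dir, "manifest_cases.txt"),
                       sep = "$", quote = FALSE, row.names = FALSE,
                       na = "", fileEncoding = "UTF-8")
  }
  list(tables = tables, manifest = manifest, vocab = vocab, dir = dir)
}

#' Assemble a generated bundle into a case set
#'
#' Convenience wrapper running deduplication and assembly on an
#' in-memory generated bundle, exactly as the pipeline does on parsed
#' files.
#'
#' @param bundle result of [generate_faers()].
#' @return a `faers_cases` bundle.
#' @export
assemble_synthetic <- function(bundle) {
  dd <- deduplicate_cases(bundle$tables$demo)
  assemble_cases(dd$demo, bundle$tables$drug, bundle$tables$reac,
                 bundle$tables$indi, bundle$tables$ther, bundle$tables$outc,
                 synonym_map = bundle$vocab$synonyms)
}

#' Compare detected signals against the generator's ground truth
#'
#' For every planted signal: whether the combined criterion fired, the
#' estimated EBGM, and whether the true relative risk is covered by
#' `[EBGM05, Inf)`. The false-signal rate is the fraction of unplanted
#' terms with at least `min_n` target events whose combined flag fired.
#'
#' @param stats_tbl a PT-level [signal_table()] computed on the bundle.
#' @param manifest manifest of the generating bundle.
#' @param min_n minimum target event count for the false-signal
#'   denominator.
#' @return list with `planted` (tibble: `pt_code`, `rr`, `detected`,
#'   `ebgm`, `ebgm05`, `covered`), `false_signal_rate`, `n_unplanted`.
#' @export
evaluate_recovery <- function(stats_tbl, manifest, min_n = 3) {
  seed_attr <- attr(stats_tbl, "synthetic_seed")
  if (!is.null(seed_attr) && !identical(seed_attr, manifest$seed)) {
    abort_fs("manifest/bundle mismatch: different generator seeds")
  }
  planted <- manifest$planted
  if (is.null(planted) || nrow(planted) == 0) {
    planted_out <- tibble::tibble(pt_code = integer(), rr = numeric(),
                                  detected = logical(), ebgm = numeric(),
                                  ebgm05 = numeric(), covered = logical())
  } else {
    m <- match(planted$pt_code, stats_tbl$pt_code)
    detected <- !is.na(m) & !is.na(stats_tbl$signal[m]) & stats_tbl$signal[m]
    ebgm <- ifelse(is.na(m), NA_real_, stats_tbl$ebgm[m])
    ebgm05 <- ifelse(is.na(m), NA_real_, stats_tbl$ebgm05[m])
    planted_out <- tibble::tibble(
      pt_code = planted$pt_code, rr = planted$rr, detected = detected,
      ebgm = ebgm, ebgm05 = ebgm05,
      covered = !is.na(ebgm05) & ebgm05 <= planted$rr)
  }
  unplanted <- stats_tbl[!(stats_tbl$pt_code %in%
                             (planted$pt_code %||% integer(0))) &
                           stats_tbl$n >= min_n, ]
  rate <- if (nrow(unplanted) > 0) mean(unplanted$signal) else 0
  list(planted = planted_out, false_signal_rate = rate,
       n_unplanted = nrow(unplanted))
}
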