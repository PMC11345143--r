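# End-to-end orchestration: ingest -> dedup -> strata -> tabulate ->
# statistics -> rank -> report, from a single configuration.

default_run_config <- function() {
  list(
    input_dir = NULL,
    files = NULL,              # named list demo/drug/reac/indi/ther/outc
    pt_file = NULL, smq_file = NULL, synonym_file = NULL,
    target_ingredients = NULL,
    strata = c("overall", "pregnancy"),
    criteria = list(),         # overrides for signal_criteria()
    pregnancy = list(pediatric_age_cutoff = 12, exclude_male = FALSE),
    top_k = 50,
    output_dir = NULL,
    full_precision = FALSE
  )
}

# locate table files: explicit `files` wins, otherwise <DIR>/<KIND>*.txt
resolve_files <- function(config) {
  kinds <- c("demo", "drug", "reac", "indi", "ther", "outc")
  if (!is.null(config$files)) return(config$files[kinds])
  if (is.null(config$input_dir)) abort_fs("config needs input_dir or files")
  out <- lapply(kinds, function(k) {
    hits <- list.files(config$input_dir, paste0("^", toupper(k), ".*\\.txt$"),
                       full.names = TRUE)
    if (length(hits) == 0) NULL else sort(hits)
  })
  names(out) <- kinds
  if (is.null(out$demo) || is.null(out$drug) || is.null(out$reac)) {
    abort_fs("input_dir must contain DEMO, DRUG and REAC files")
  }
  out
}

parse_many <- function(paths, schema) {
  if (is.null(paths)) return(NULL)
  dplyr::bind_rows(lapply(paths, parse_faers_table, schema = schema))
}

round_stats <- function(tbl, digits = 2) {
  num <- vapply(tbl, is.numeric, TRUE) & !names(tbl) %in% c("n", "pt_code")
  tbl[num] <- lapply(tbl[num], round, digits = digits)
  tbl
}

#' Run the full disproportionality analysis
#'
#' Orchestrates the pipeline from a configuration (an R list or the path
#' of a YAML file with the same fields): parse the quarterly tables,
#' deduplicate case versions, assemble report cases, build the pregnancy
#' cohort where requested, tabulate events, compute the four
#' disproportionality estimators per PT and SOC, evaluate the combined
#' criterion and rank signals; descriptive summaries (characteristics,
#' annual counts, top-K term frequencies) are produced for the target
#' reports of each stratum. The run is a pure function of the inputs:
#' identical inputs give byte-identical outputs.
#'
#' Config fields: `input_dir` (or `files`, a named list of paths),
#' `pt_file`, `smq_file`, `synonym_file`, `target_ingredients`, `strata`
#' (subset of `"overall"`, `"pregnancy"`), `criteria` (threshold
#' overrides), `pregnancy` (`pediatric_age_cutoff`, `exclude_male`),
#' `top_k`, `output_dir`, `full_precision`.
#'
#' @param config list or YAML file path.
#' @return (invisibly) list with per-stratum signal tables, descriptive
#'   summaries and the audit log; CSV/JSON artifacts are written to
#'   `output_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_run_config(), config)
  if (is.null(config$target_ingredients)) {
    abort_fs("config: target_ingredients is required")
  }
  stopifnot(length(config$strata) > 0)

  files <- resolve_files(config)
  dict <- load_dictionary(config$pt_file, config$smq_file)
  syn <- load_synonym_map(config$synonym_file, config$target_ingredients)
  audit <- list()

  demo <- parse_many(files$demo, "demo")
  drug <- parse_many(files$drug, "drug")
  reac <- parse_many(files$reac, "reac")
  indi <- parse_many(files$indi, "indi")
  ther <- parse_many(files$ther, "ther")
  outc <- parse_many(files$outc, "outc")
  audit$demo_rows <- nrow(demo)

  dd <- deduplicate_cases(demo)
  audit$reports_after_dedup <- nrow(dd$demo)
  audit$duplicate_versions_removed <- dd$n_removed

  cases <- assemble_cases(dd$demo, drug, reac, indi, ther, outc,
                          synonym_map = syn)
  audit$reports_assembled <- nrow(cases$cases)
  audit$events_total <- nrow(cases$reactions)

  target_ids <- target_report_ids(cases, config$target_ingredients)
  audit$reports_target <- length(target_ids)

  lists <- pregnancy_term_lists()
  criteria <- do.call(signal_criteria, config$criteria)
  digits <- if (isTRUE(config$full_precision)) 10 else 2

  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(tbl, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    utils::write.csv(tbl, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }

  results <- list()
  for (stratum in config$strata) {
    if (stratum == "pregnancy") {
      cohort <- build_cohort(
        cases, dict, lists,
        pediatric_age_cutoff = config$pregnancy$pediatric_age_cutoff,
        exclude_male = isTRUE(config$pregnancy$exclude_male))
      audit$pregnancy <- as.list(cohort$audit)
      ids <- cohort$cohort_ids
      if (length(ids) == 0) {
        warning("pregnancy stratum is empty: emitting empty signal tables")
      }
      if (!is.null(out_dir)) {
        emit(cohort$labels[cohort$labels$label != "non_pregnancy", ],
             "cohort_pregnancy")
      }
    } else {
      ids <- cases$cases$primaryid
    }
    counts <- tabulate_events(cases, config$target_ingredients, dict,
                              stratum_ids = ids, stratum = stratum)
    audit[[paste0("events_", stratum)]] <- counts$N
    audit[[paste0("target_events_", stratum)]] <- counts$drug_total

    sig_pt <- round_stats(signal_table(counts, "pt", criteria), digits)
    sig_soc <- round_stats(signal_table(counts, "soc", criteria), digits)
    ranked <- rank_signals(sig_pt, top_k = config$top_k)
    topk <- top_terms(counts, k = config$top_k, level = "pt")

    stratum_cases <- subset_cases(cases, intersect(ids, target_ids))
    summary <- summarize_characteristics(stratum_cases,
                                         config$target_ingredients)
    annual <- annual_counts(stratum_cases)

    emit(sig_pt, paste0("signals_", stratum, "_pt"))
    emit(sig_soc, paste0("signals_", stratum, "_soc"))
    emit(ranked, paste0("signals_", stratum, "_ranked"))
    emit(topk, paste0("top_terms_", stratum))
    emit(annual, paste0("annual_counts_", stratum))
    if (!is.null(out_dir)) {
      blocks <- c("sex", "age", "reporter", "country", "route", "outcomes")
      char_tbl <- dplyr::bind_rows(lapply(blocks, function(b) {
        tibble::tibble(block = b, summary[[b]])
      }))
      emit(char_tbl, paste0("characteristics_", stratum))
    }
    results[[stratum]] <- list(counts = counts, signals_pt = sig_pt,
                               signals_soc = sig_soc, ranked = ranked,
                               top_terms = topk, characteristics = summary,
                               annual = annual)
  }
  if (!is.null(out_dir)) {
    writeLines(jsonlite::toJSON(audit, auto_unbox = TRUE, pretty = TRUE),
               file.path(out_dir, "audit.json"))
  }
  invisible(list(results = results, audit = audit, config = config))
}
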