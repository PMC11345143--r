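# Reading FAERS-dialect quarterly tables, deduplicating case versions and
# assembling relational report-case bundles restricted to primary-suspect
# exposures.

# Required columns per table kind. Extra columns are tolerated; column
# aliases across database-era schema changes can be supplied to
# parse_faers_table(aliases=).
faers_schemas <- list(
  demo = c("primaryid", "caseid", "fda_dt"),
  drug = c("primaryid", "drugname", "role_cod"),
  reac = c("primaryid", "pt"),
  indi = c("primaryid", "indi_pt"),
  ther = c("primaryid", "start_dt"),
  outc = c("primaryid", "outc_cod")
)

#' Parse one FAERS-dialect quarterly table
#'
#' Reads a "$"-delimited ASCII file with a single header row. Empty
#' fields become `NA`; dates stay as 8-digit strings and are validated
#' lazily downstream. Rows whose field count does not match the header
#' are skipped with a message; the skip count is attached as attribute
#' `"skipped"`. A missing required column is a hard error naming it.
#'
#' @param path file path.
#' @param schema table kind: one of `"demo"`, `"drug"`, `"reac"`,
#'   `"indi"`, `"ther"`, `"outc"`.
#' @param aliases optional named character vector mapping file column
#'   names to canonical names (e.g. `c(isr = "primaryid")`).
#' @param sep field separator, default `"$"`.
#' @return tibble of character columns with attribute `"skipped"`.
#' @export
parse_faers_table <- function(path, schema, aliases = NULL, sep = "$") {
  schema <- match.arg(schema, names(faers_schemas))
  if (!file.exists(path)) abort_fs("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) abort_fs("empty file: ", path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  header <- tolower(trimws(parts[[1]]))
  if (!is.null(aliases)) {
    hit <- header %in% names(aliases)
    header[hit] <- unname(aliases[header[hit]])
  }
  req <- faers_schemas[[schema]]
  miss <- setdiff(req, header)
  if (length(miss) > 0) {
    abort_fs("table '", schema, "' (", basename(path),
             ") missing required column(s): ", paste(miss, collapse = ", "))
  }
  body <- parts[-1]
  nf <- lengths(body)
  # trailing empty field is dropped by strsplit; pad rows one short
  short <- nf == length(header) - 1L
  if (any(short)) {
    body[short] <- lapply(body[short], function(p) c(p, ""))
    nf[short] <- length(header)
  }
  bad <- nf != length(header)
  n_skipped <- sum(bad)
  if (n_skipped > 0) {
    message(sprintf("%s: skipped %d malformed row(s)", basename(path),
                    n_skipped))
    body <- body[!bad]
  }
  cols <- lapply(seq_along(header), function(i) {
    v <- vapply(body, `[[`, "", i)
    v[!nzchar(trimws(v))] <- NA_character_
    v
  })
  names(cols) <- header
  out <- tibble::as_tibble(cols)
  attr(out, "skipped") <- n_skipped
  out
}

#' Deduplicate case versions
#'
#' A spontaneous-report case may be submitted in several versions (same
#' `caseid`, different `primaryid`). Exactly one record per case is kept:
#' the one with the latest receipt date `fda_dt`, ties broken by the
#' largest `primaryid`. Records missing `caseid` are treated as singleton
#' cases with a warning.
#'
#' @param demo DEMO tibble with `primaryid`, `caseid`, `fda_dt`.
#' @return list with `demo` (deduplicated tibble), `removed` (tibble of
#'   removed `primaryid`/`caseid`) and `n_removed`.
#' @export
deduplicate_cases <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  demo <- tibble::as_tibble(demo)
  no_case <- is.na(demo$caseid)
  if (any(no_case)) {
    warning(sum(no_case), " record(s) missing caseid treated as singleton cases")
    demo$caseid[no_case] <- paste0("__singleton_", demo$primaryid[no_case])
  }
  ord <- order(demo$caseid,
               -xtfrm(as_num(demo$fda_dt)),
               -xtfrm(as_num(demo$primaryid)))
  sorted <- demo[ord, ]
  keep <- !duplicated(sorted$caseid)
  removed <- sorted[!keep, c("primaryid", "caseid")]
  list(demo = sorted[keep, ][order(as_num(sorted$primaryid[keep])), ],
       removed = removed,
       n_removed = nrow(removed))
}

# FAERS age units -> years multiplier
age_unit_factor <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
                     DY = 1 / 365.25, HR = 1 / 8766)

# Convert FAERS age + unit code to years; unparseable or negative -> NA.
age_to_years <- function(age, age_cod) {
  a <- as_num(age)
  f <- age_unit_factor[toupper(ifelse(is.na(age_cod), "YR", age_cod))]
  f[is.na(f)] <- NA_real_
  out <- a * unname(f)
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Assemble relational report cases from parsed tables
#'
#' Joins the child tables onto the (deduplicated) DEMO table by
#' `primaryid`, producing a `faers_cases` bundle: a demographics tibble
#' plus drug, reaction, indication, outcome entries. Reaction PT codes
#' are de-duplicated within a report; reports with no reactions are
#' dropped (a report must describe at least one adverse event); child
#' rows with no DEMO parent (e.g. rows belonging to superseded case
#' versions) are dropped. All drop counts are kept in the `counters`
#' element.
#'
#' @param demo,drug,reac,indi,ther,outc parsed tibbles (see
#'   [parse_faers_table()]); `indi`, `ther`, `outc` may be `NULL`.
#' @param synonym_map optional [drug_synonym_map()]; when given, each
#'   drug entry gains a normalized `ingredient` (`NA` if unknown).
#' @return object of class `faers_cases`: list of tibbles `cases`,
#'   `drugs`, `reactions`, `indications`, `outcomes` plus `counters`.
#' @export
assemble_cases <- function(demo, drug, reac, indi = NULL, ther = NULL,
                           outc = NULL, synonym_map = NULL) {
  demo <- tibble::as_tibble(demo)
  ids <- demo$primaryid
  counters <- list()

  keep_children <- function(tab, what) {
    if (is.null(tab)) return(NULL)
    orphan <- !(tab$primaryid %in% ids)
    counters[[paste0("orphan_", what)]] <<- sum(orphan)
    tab[!orphan, , drop = FALSE]
  }
  drug <- keep_children(tibble::as_tibble(drug), "drug")
  reac <- keep_children(tibble::as_tibble(reac), "reac")
  indi <- if (!is.null(indi)) keep_children(tibble::as_tibble(indi), "indi")
  ther <- if (!is.null(ther)) keep_children(tibble::as_tibble(ther), "ther")
  outc <- if (!is.null(outc)) keep_children(tibble::as_tibble(outc), "outc")

  reactions <- dplyr::distinct(
    tibble::tibble(primaryid = reac$primaryid,
                   pt_code = as.integer(as_num(reac$pt)))
  )
  reactions <- reactions[!is.na(reactions$pt_code), ]

  # invariant: a report must carry at least one reaction
  has_reac <- ids %in% reactions$primaryid
  counters$no_reaction <- sum(!has_reac)
  demo <- demo[has_reac, ]
  ids <- demo$primaryid

  drugs <- tibble::tibble(
    primaryid = drug$primaryid,
    drug_seq = if ("drug_seq" %in% names(drug)) as.integer(as_num(drug$drug_seq))
               else stats::ave(seq_len(nrow(drug)), drug$primaryid, FUN = seq_along),
    raw_name = drug$drugname,
    role = toupper(ifelse(is.na(drug$role_cod), "C", drug$role_cod)),
    route = fold_name(ifelse(is.na(drug[["route"]] %||% NA_character_),
                             "unk", drug[["route"]] %||% "unk"))
  )
  if (!all(drugs$role %in% c("PS", "SS", "C", "I"))) {
    bad <- unique(drugs$role[!drugs$role %in% c("PS", "SS", "C", "I")])
    abort_fs("unknown drug role code(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(synonym_map)) {
    ai <- drug[["prod_ai"]]
    lookup <- normalize_drug_name(drugs$raw_name, synonym_map)
    if (!is.null(ai)) {
      via_ai <- normalize_drug_name(ai, synonym_map)
      lookup <- ifelse(is.na(lookup), via_ai, lookup)
    }
    drugs$ingredient <- lookup
  } else {
    drugs$ingredient <- NA_character_
  }
  # therapy start dates: join by (primaryid, drug_seq) when available,
  # else earliest start date of the report
  if (!is.null(ther) && nrow(ther) > 0) {
    if ("dsg_drug_seq" %in% names(ther)) {
      th <- tibble::tibble(primaryid = ther$primaryid,
                           drug_seq = as.integer(as_num(ther$dsg_drug_seq)),
                           start_dt = ther$start_dt)
      th <- th[!duplicated(th[c("primaryid", "drug_seq")]), ]
      drugs <- dplyr::left_join(drugs, th, by = c("primaryid", "drug_seq"))
    } else {
      th <- ther[is_date8(ther$start_dt), ]
      th <- if (nrow(th) > 0) {
        th |>
          dplyr::group_by(.data$primaryid) |>
          dplyr::summarise(start_dt = min(.data$start_dt), .groups = "drop")
      } else {
        tibble::tibble(primaryid = character(), start_dt = character())
      }
      drugs <- dplyr::left_join(drugs, th, by = "primaryid")
    }
  } else {
    drugs$start_dt <- NA_character_
  }
  drugs <- drugs[drugs$primaryid %in% ids, ]

  indications <- if (!is.null(indi) && nrow(indi) > 0) {
    out <- dplyr::distinct(
      tibble::tibble(primaryid = indi$primaryid,
                     pt_code = as.integer(as_num(indi$indi_pt))))
    out[!is.na(out$pt_code) & out$primaryid %in% ids, ]
  } else {
    tibble::tibble(primaryid = character(), pt_code = integer())
  }

  outcomes <- if (!is.null(outc) && nrow(outc) > 0) {
    out <- dplyr::distinct(
      tibble::tibble(primaryid = outc$primaryid,
                     outc_cod = toupper(outc$outc_cod)))
    out[!is.na(out$outc_cod) & out$primaryid %in% ids, ]
  } else {
    tibble::tibble(primaryid = character(), outc_cod = character())
  }

  sex <- toupper(demo[["sex"]] %||% rep(NA_character_, nrow(demo)))
  sex[is.na(sex) | !sex %in% c("F", "M")] <- "UNK"
  country <- demo[["occr_country"]] %||% rep(NA_character_, nrow(demo))
  rep_country <- demo[["reporter_country"]] %||% rep(NA_character_, nrow(demo))
  country <- ifelse(is.na(country), rep_country, country)
  country[is.na(country)] <- "UNK"
  reporter <- demo[["occp_cod"]] %||% rep(NA_character_, nrow(demo))
  reporter[is.na(reporter)] <- "UNK"

  cases <- tibble::tibble(
    primaryid = demo$primaryid,
    caseid = demo$caseid,
    fda_dt = demo$fda_dt,
    event_dt = demo[["event_dt"]] %||% rep(NA_character_, nrow(demo)),
    age_years = age_to_years(demo[["age"]] %||% rep(NA_character_, nrow(demo)),
                             demo[["age_cod"]] %||% rep(NA_character_, nrow(demo))),
    sex = sex,
    reporter = reporter,
    country = country,
    year = date_year(demo$fda_dt)
  )

  structure(list(cases = cases, drugs = drugs, reactions = reactions,
                 indications = indications, outcomes = outcomes,
                 counters = counters),
            class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("<faers_cases> ", nrow(x$cases), " reports, ",
      nrow(x$reactions), " distinct (report, PT) events, ",
      nrow(x$drugs), " drug entries\n", sep = "")
  invisible(x)
}

#' Subset a case bundle to a set of reports
#'
#' @param cases a `faers_cases` bundle.
#' @param ids primaryids to keep.
#' @return a `faers_cases` bundle restricted to `ids`.
#' @export
subset_cases <- function(cases, ids) {
  stopifnot(inherits(cases, "faers_cases"))
  out <- cases
  out$cases <- cases$cases[cases$cases$primaryid %in% ids, ]
  for (nm in c("drugs", "reactions", "indications", "outcomes")) {
    out[[nm]] <- cases[[nm]][cases[[nm]]$primaryid %in% ids, ]
  }
  out
}

#' Restrict to reports with a target drug as primary suspect
#'
#' Keeps reports where at least one drug entry has a normalized
#' ingredient in the target class AND role code `PS`. A report carrying
#' the target only as concomitant/interacting/secondary is excluded.
#' Idempotent.
#'
#' @param cases a `faers_cases` bundle (assembled with a synonym map).
#' @param target_ingredients non-empty character vector of normalized
#'   ingredient labels.
#' @return a `faers_cases` bundle.
#' @export
filter_target_reports <- function(cases, target_ingredients) {
  stopifnot(inherits(cases, "faers_cases"))
  if (length(target_ingredients) == 0) {
    abort_fs("target ingredient set must be non-empty")
  }
  hit <- cases$drugs$role == "PS" &
    !is.na(cases$drugs$ingredient) &
    cases$drugs$ingredient %in% target_ingredients
  subset_cases(cases, unique(cases$drugs$primaryid[hit]))
}

# primaryids of reports with a PS target drug (helper used by tabulation)
target_report_ids <- function(cases, target_ingredients) {
  hit <- cases$drugs$role == "PS" &
    !is.na(cases$drugs$ingredient) &
    cases$drugs$ingredient %in% target_ingredients
  unique(cases$drugs$primaryid[hit])
}
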