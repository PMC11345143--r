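# Domain vocabulary: MedDRA-like preferred-term (PT) hierarchy, SMQ code
# sets, pregnancy-retrieval code lists and the drug synonym dictionary.

#' Construct a term dictionary from PT and SMQ tables
#'
#' A term dictionary bundles the preferred-term index (PT code, PT name,
#' system organ class) with the SMQ membership table (SMQ code -> set of
#' member PT codes). Every PT maps to exactly one SOC; every SMQ member
#' must exist in the PT table.
#'
#' @param pt data frame with columns `pt_code`, `pt_name`, `soc_name`.
#' @param smq data frame with columns `smq_code`, `pt_code`; may have zero
#'   rows when no SMQs are defined.
#' @return an object of class `term_dictionary`: a list with tibbles `pt`
#'   and `smq` plus `smq_sets`, a named list of integer PT-code vectors.
#' @export
term_dictionary <- function(pt, smq = NULL) {
  pt <- tibble::as_tibble(pt)
  stopifnot(all(c("pt_code", "pt_name", "soc_name") %in% names(pt)))
  pt$pt_code <- as.integer(pt$pt_code)
  if (anyNA(pt$pt_code)) abort_fs("non-numeric PT code in PT table")
  dup <- pt$pt_code[duplicated(pt$pt_code)]
  if (length(dup) > 0) {
    abort_fs("duplicate PT code(s) in dictionary: ",
             paste(unique(dup), collapse = ", "))
  }
  if (is.null(smq)) {
    smq <- tibble::tibble(smq_code = integer(), pt_code = integer())
  }
  smq <- tibble::as_tibble(smq)
  stopifnot(all(c("smq_code", "pt_code") %in% names(smq)))
  smq$smq_code <- as.integer(smq$smq_code)
  smq$pt_code <- as.integer(smq$pt_code)
  missing_pt <- setdiff(smq$pt_code, pt$pt_code)
  if (length(missing_pt) > 0) {
    abort_fs("SMQ member PT(s) absent from PT table: ",
             paste(missing_pt, collapse = ", "))
  }
  smq <- dplyr::distinct(smq, .data$smq_code, .data$pt_code)
  sets <- split(smq$pt_code, smq$smq_code)
  structure(list(pt = pt, smq = smq, smq_sets = sets),
            class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("<term_dictionary> ", nrow(x$pt), " PTs, ",
      length(unique(x$pt$soc_name)), " SOCs, ",
      length(x$smq_sets), " SMQs\n", sep = "")
  invisible(x)
}

# Autodetect the field separator of a dictionary file ("$" or tab).
detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("$", first, fixed = TRUE)) "$" else "\t"
}

read_delim_strict <- function(path, sep) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) abort_fs("empty file: ", path)
  parts <- strsplit(lines, sep, fixed = TRUE)
  header <- parts[[1]]
  body <- parts[-1]
  bad <- vapply(body, length, 1L) != length(header)
  if (any(bad)) abort_fs("malformed row(s) in ", path)
  cols <- lapply(seq_along(header), function(i) {
    vapply(body, `[[`, "", i)
  })
  names(cols) <- header
  tibble::as_tibble(cols)
}

#' Load a term dictionary from delimited files
#'
#' Files are "$"- or tab-delimited (autodetected) with one header row:
#' the PT table has columns `pt_code`, `pt_name`, `soc_name`; the SMQ
#' table has `smq_code`, `pt_code`. A duplicate PT code, or an SMQ member
#' PT absent from the PT table, is a hard error naming the code.
#'
#' @param pt_file path to the PT table.
#' @param smq_file path to the SMQ membership table, or `NULL`.
#' @return a [term_dictionary()].
#' @export
load_dictionary <- function(pt_file, smq_file = NULL) {
  pt <- read_delim_strict(pt_file, detect_sep(pt_file))
  req <- c("pt_code", "pt_name", "soc_name")
  if (!all(req %in% names(pt))) {
    abort_fs("PT table missing column(s): ",
             paste(setdiff(req, names(pt)), collapse = ", "))
  }
  smq <- NULL
  if (!is.null(smq_file)) {
    smq <- read_delim_strict(smq_file, detect_sep(smq_file))
    if (!all(c("smq_code", "pt_code") %in% names(smq))) {
      abort_fs("SMQ table missing column(s): ",
               paste(setdiff(c("smq_code", "pt_code"), names(smq)),
                     collapse = ", "))
    }
  }
  term_dictionary(pt, smq)
}

#' Write a term dictionary back to delimited files
#'
#' Inverse of [load_dictionary()]; reloading the written files yields the
#' same term sets.
#'
#' @param dict a [term_dictionary()].
#' @param pt_file,smq_file output paths.
#' @param sep field separator, default `"$"`.
#' @export
write_dictionary <- function(dict, pt_file, smq_file, sep = "$") {
  utils::write.table(dict$pt, pt_file, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(dict$smq, smq_file, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dict)
}

#' PT-code to SOC-name lookup
#'
#' @param dict a [term_dictionary()].
#' @return named character vector: `names()` are PT codes, values SOC names.
#' @export
pt_to_soc <- function(dict) {
  stats::setNames(dict$pt$soc_name, dict$pt$pt_code)
}

#' Union of member PTs of a set of SMQs
#'
#' @param dict a [term_dictionary()].
#' @param smq_codes integer SMQ codes; every code must be defined in the
#'   dictionary (unknown code is a hard error).
#' @return integer vector of member PT codes.
#' @export
smq_members <- function(dict, smq_codes) {
  smq_codes <- as.integer(smq_codes)
  unknown <- setdiff(smq_codes, as.integer(names(dict$smq_sets)))
  if (length(unknown) > 0) {
    abort_fs("unknown SMQ code(s): ", paste(unknown, collapse = ", "))
  }
  sort(unique(unlist(dict$smq_sets[as.character(smq_codes)], use.names = FALSE)))
}

#' Code lists defining pregnancy-related report retrieval
#'
#' The defaults are the PT and SMQ codes used to retrieve and classify
#' pregnancy-related spontaneous reports: six SMQs searched in the
#' adverse-event (reaction) fields, three of them also searched in the
#' indication fields, a list of maternal/foetal exposure PTs whose
#' presence makes a report *definitive* pregnancy-related, a list of
#' paternal-exposure PTs that excludes a report, and the administration
#' route label that also counts as definitive evidence.
#'
#' @param definitive_pts integer PT codes of maternal/foetal exposure terms.
#' @param paternal_pts integer PT codes of paternal exposure terms.
#' @param event_smqs integer SMQ codes searched over reactions.
#' @param indication_smqs integer SMQ codes searched over indications.
#' @param transplacental_route route label (folded) counting as definitive.
#' @return object of class `pregnancy_term_lists`.
#' @export
pregnancy_term_lists <- function(
    definitive_pts = c(10071407L, 10071409L, 10071406L, 10071408L,
                       10071404L, 10073513L, 10071415L, 10071405L,
                       10026923L, 10064998L),
    paternal_pts = c(10050425L, 10071403L, 10080091L, 10080092L,
                     10080093L, 10084938L),
    event_smqs = c(20000077L, 20000186L, 20000190L, 20000191L,
                   20000192L, 20000193L),
    indication_smqs = c(20000186L, 20000190L, 20000193L),
    transplacental_route = "transplacental") {
  definitive_pts <- as.integer(definitive_pts)
  paternal_pts <- as.integer(paternal_pts)
  if (length(intersect(definitive_pts, paternal_pts)) > 0) {
    abort_fs("definitive and paternal PT lists must be disjoint")
  }
  structure(list(definitive_pts = definitive_pts,
                 paternal_pts = paternal_pts,
                 event_smqs = as.integer(event_smqs),
                 indication_smqs = as.integer(indication_smqs),
                 transplacental_route = fold_name(transplacental_route)),
            class = "pregnancy_term_lists")
}

#' Drug synonym dictionary
#'
#' Maps raw drug-name strings (generic names, brand names, active
#' ingredients) to a normalized ingredient label. Lookup keys are folded
#' with [fold_name()]; every target ingredient must be reachable, i.e.
#' appear as at least one entry value.
#'
#' @param entries two-column data frame (`raw_name`, `ingredient`) or a
#'   named character vector (names = raw, values = ingredient).
#' @param target_ingredients character vector of normalized labels making
#'   up the study drug class.
#' @return object of class `drug_synonym_map`.
#' @export
drug_synonym_map <- function(entries, target_ingredients) {
  if (is.data.frame(entries)) {
    stopifnot(all(c("raw_name", "ingredient") %in% names(entries)))
    map <- stats::setNames(as.character(entries$ingredient),
                           fold_name(entries$raw_name))
  } else {
    map <- stats::setNames(as.character(entries), fold_name(names(entries)))
  }
  if (anyDuplicated(names(map))) {
    keep <- !duplicated(names(map))
    map <- map[keep]
  }
  # close the map under its own outputs so normalization is idempotent
  ident <- unique(unname(map))
  add <- setdiff(fold_name(ident), names(map))
  if (length(add) > 0) {
    extra <- stats::setNames(ident[match(add, fold_name(ident))], add)
    map <- c(map, extra)
  }
  target_ingredients <- unique(as.character(target_ingredients))
  miss <- setdiff(target_ingredients, unname(map))
  if (length(miss) > 0) {
    abort_fs("target ingredient(s) with no synonym entry: ",
             paste(miss, collapse = ", "))
  }
  structure(list(entries = map, target_ingredients = target_ingredients),
            class = "drug_synonym_map")
}

#' Load a drug synonym map from a delimited file
#'
#' @param path "$"- or tab-delimited file with header `raw_name`, `ingredient`.
#' @param target_ingredients see [drug_synonym_map()].
#' @export
load_synonym_map <- function(path, target_ingredients) {
  tab <- read_delim_strict(path, detect_sep(path))
  if (!all(c("raw_name", "ingredient") %in% names(tab))) {
    abort_fs("synonym table missing column(s): ",
             paste(setdiff(c("raw_name", "ingredient"), names(tab)),
                   collapse = ", "))
  }
  drug_synonym_map(tab, target_ingredients)
}

#' Normalize a raw drug name to its ingredient label
#'
#' Case-insensitive, punctuation/whitespace-folded exact lookup in the
#' synonym map; absence is a valid result (`NA`). Idempotent on its own
#' outputs: [drug_synonym_map()] closes the entry set so every ingredient
#' label maps to itself.
#'
#' @param raw character vector of raw drug names.
#' @param map a [drug_synonym_map()].
#' @return character vector of normalized ingredients, `NA` where unknown.
#' @export
normalize_drug_name <- function(raw, map) {
  stopifnot(inherits(map, "drug_synonym_map"))
  out <- unname(map$entries[fold_name(raw)])
  out[!nzchar(trimws(as.character(raw))) | is.na(raw)] <- NA_character_
  out
}
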