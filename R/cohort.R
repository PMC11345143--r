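# SMQ-based retrieval and classification of pregnancy-related reports:
# reports are retrieved by SMQ hits in the reaction or indication fields,
# then partitioned into definitive / other / excluded; everything else is
# non-pregnancy.

#' Flag reports whose reactions hit the pregnancy event SMQs
#'
#' `TRUE` for a report iff its reaction PT set intersects the union of
#' member PTs of the event SMQs.
#'
#' @param cases a `faers_cases` bundle.
#' @param dict a [term_dictionary()] defining the SMQ member sets.
#' @param lists a [pregnancy_term_lists()].
#' @return logical vector aligned with `cases$cases` rows.
#' @export
flag_smq_events <- function(cases, dict, lists) {
  members <- smq_members(dict, lists$event_smqs)
  hit_ids <- unique(cases$reactions$primaryid[
    cases$reactions$pt_code %in% members])
  cases$cases$primaryid %in% hit_ids
}

#' Flag reports whose indications hit the pregnancy indication SMQs
#'
#' As [flag_smq_events()] but over the indication PT codes and the
#' (smaller) indication SMQ list.
#'
#' @inheritParams flag_smq_events
#' @return logical vector aligned with `cases$cases` rows.
#' @export
flag_smq_indications <- function(cases, dict, lists) {
  members <- smq_members(dict, lists$indication_smqs)
  hit_ids <- unique(cases$indications$primaryid[
    cases$indications$pt_code %in% members])
  cases$cases$primaryid %in% hit_ids
}

#' Classify SMQ-retrieved reports as pregnancy-related
#'
#' Partitions every report into one of four labels:
#' \describe{
#'   \item{non_pregnancy}{no SMQ evidence in reactions or indications.}
#'   \item{excluded}{SMQ evidence but a paternal-exposure PT, a
#'     pediatric age (below `pediatric_age_cutoff`), or -- when
#'     `exclude_male = TRUE` -- male sex.}
#'   \item{definitive}{a maternal/foetal exposure PT among reactions or
#'     indications, or a transplacental administration route.}
#'   \item{other}{SMQ evidence only.}
#' }
#' Exclusion rules take precedence over the definitive/other split;
#' definitive evidence never rescues an excluded report. All rules that
#' fired are recorded in `reasons` (semicolon-separated), so the default
#' policy of retaining male/unknown-sex reports still annotates them.
#' Classification is a pure function of the case bundle and the
#' configuration.
#'
#' @inheritParams flag_smq_events
#' @param pediatric_age_cutoff age in years below which an SMQ-retrieved
#'   report is treated as a pediatric-treatment report and excluded.
#' @param exclude_male if `TRUE`, male-sex reports are excluded rather
#'   than merely annotated.
#' @return tibble with `primaryid`, `label`, `reasons`.
#' @export
classify_pregnancy <- function(cases, dict, lists,
                               pediatric_age_cutoff = 12,
                               exclude_male = FALSE) {
  stopifnot(inherits(lists, "pregnancy_term_lists"))
  cc <- cases$cases
  ev <- flag_smq_events(cases, dict, lists)
  ind <- flag_smq_indications(cases, dict, lists)

  term_ids <- function(codes) {
    unique(c(cases$reactions$primaryid[cases$reactions$pt_code %in% codes],
             cases$indications$primaryid[cases$indications$pt_code %in% codes]))
  }
  paternal <- cc$primaryid %in% term_ids(lists$paternal_pts)
  def_pt <- cc$primaryid %in% term_ids(lists$definitive_pts)
  transpl <- cc$primaryid %in% unique(cases$drugs$primaryid[
    cases$drugs$route == lists$transplacental_route])
  pediatric <- !is.na(cc$age_years) & cc$age_years < pediatric_age_cutoff
  male <- cc$sex == "M"

  candidate <- ev | ind
  excluded <- candidate & (paternal | pediatric | (exclude_male & male))
  definitive <- candidate & !excluded & (def_pt | transpl)
  other <- candidate & !excluded & !definitive

  label <- rep("non_pregnancy", nrow(cc))
  label[other] <- "other"
  label[definitive] <- "definitive"
  label[excluded] <- "excluded"

  reason_mat <- cbind(
    smq_event = ev, smq_indication = ind, definitive_pt = def_pt,
    transplacental_route = transpl, paternal = paternal,
    pediatric = pediatric,
    ineligible_demographics = male & candidate
  )
  reasons <- vapply(seq_len(nrow(reason_mat)), function(i) {
    paste(colnames(reason_mat)[reason_mat[i, ]], collapse = ";")
  }, character(1))
  tibble::tibble(primaryid = cc$primaryid, label = label, reasons = reasons)
}

#' Build the pregnancy cohort with audit counts
#'
#' Retrieves reports by SMQ evidence (reaction and indication fields),
#' removes duplicates between the two retrieval routes (a report hit by
#' both is counted once), applies the exclusion rules, and returns the
#' cohort = definitive union other. Audit counts mirror the retrieval
#' flow: SMQ hits per field, their union, and the size of each partition
#' cell.
#'
#' @inheritParams classify_pregnancy
#' @return object of class `pregnancy_cohort`: list with `cohort_ids`
#'   (primaryids of the final cohort), `labels` (see
#'   [classify_pregnancy()]) and `audit` (named integer counts).
#' @export
build_cohort <- function(cases, dict, lists = pregnancy_term_lists(),
                         pediatric_age_cutoff = 12, exclude_male = FALSE) {
  labels <- classify_pregnancy(cases, dict, lists,
                               pediatric_age_cutoff = pediatric_age_cutoff,
                               exclude_male = exclude_male)
  ev <- flag_smq_events(cases, dict, lists)
  ind <- flag_smq_indications(cases, dict, lists)
  tab <- table(factor(labels$label, levels = c("definitive", "other",
                                               "excluded", "non_pregnancy")))
  audit <- c(
    smq_event_hits = sum(ev),
    smq_indication_hits = sum(ind),
    union = sum(ev | ind),
    definitive = unname(tab[["definitive"]]),
    excluded = unname(tab[["excluded"]]),
    other = unname(tab[["other"]]),
    final = unname(tab[["definitive"]] + tab[["other"]])
  )
  cohort_ids <- labels$primaryid[labels$label %in% c("definitive", "other")]
  structure(list(cohort_ids = cohort_ids, labels = labels, audit = audit),
            class = "pregnancy_cohort")
}

#' @export
print.pregnancy_cohort <- function(x, ...) {
  cat("<pregnancy_cohort> final =", x$audit[["final"]],
      "(definitive", x$audit[["definitive"]], "+ other",
      x$audit[["other"]], "), excluded", x$audit[["excluded"]], "\n")
  invisible(x)
}
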