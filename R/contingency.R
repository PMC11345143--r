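# Event-level 2x2 contingency tables for (drug, PT) and (drug, SOC)
# pairs within a stratum. The counting unit is the distinct (report, PT)
# pair: a report with k distinct reaction PTs contributes k events to the
# grand total N.

#' Tabulate adverse events within a stratum
#'
#' Counts distinct (report, PT) events for every PT and SOC in a stratum
#' of reports. Target events are those occurring in reports where a
#' target-class drug is the primary suspect. SOC counts sum the events of
#' their member PTs (no per-report collapsing, which conserves N); a PT
#' with no SOC mapping is counted at PT level and pooled under
#' `"(unmapped)"` at SOC level.
#'
#' @param cases a `faers_cases` bundle.
#' @param target_ingredients normalized ingredient labels of the target
#'   drug class.
#' @param dict optional [term_dictionary()] providing the PT -> SOC map
#'   and PT names.
#' @param stratum_ids optional primaryids restricting the stratum (e.g. a
#'   pregnancy cohort); default all reports.
#' @param stratum label stored with the counts.
#' @return object of class `event_counts`: list with tibbles `pt`
#'   (`pt_code`, `term`, `soc`, `a`, `term_total`) and `soc` (`term`,
#'   `a`, `term_total`), plus `drug_total`, `N` and `stratum`.
#' @export
tabulate_events <- function(cases, target_ingredients, dict = NULL,
                            stratum_ids = NULL, stratum = "overall") {
  stopifnot(inherits(cases, "faers_cases"))
  if (!is.null(stratum_ids)) cases <- subset_cases(cases, stratum_ids)
  ev <- cases$reactions # already distinct (report, PT)
  tids <- target_report_ids(cases, target_ingredients)
  ev$target <- ev$primaryid %in% tids

  pt <- ev |>
    dplyr::group_by(.data$pt_code) |>
    dplyr::summarise(a = sum(.data$target), term_total = dplyr::n(),
                     .groups = "drop")
  if (!is.null(dict)) {
    soc_map <- pt_to_soc(dict)
    pt$soc <- unname(soc_map[as.character(pt$pt_code)])
    name_map <- stats::setNames(dict$pt$pt_name, dict$pt$pt_code)
    pt$term <- unname(name_map[as.character(pt$pt_code)])
    pt$term[is.na(pt$term)] <- as.character(pt$pt_code[is.na(pt$term)])
  } else {
    pt$soc <- NA_character_
    pt$term <- as.character(pt$pt_code)
  }
  soc <- pt |>
    dplyr::mutate(soc_lab = ifelse(is.na(.data$soc), "(unmapped)", .data$soc)) |>
    dplyr::group_by(term = .data$soc_lab) |>
    dplyr::summarise(a = sum(.data$a), term_total = sum(.data$term_total),
                     .groups = "drop")
  structure(list(
    pt = pt[, c("pt_code", "term", "soc", "a", "term_total")],
    soc = soc,
    drug_total = sum(ev$target),
    N = nrow(ev),
    stratum = stratum
  ), class = "event_counts")
}

#' @export
print.event_counts <- function(x, ...) {
  cat("<event_counts> stratum:", x$stratum, "-", nrow(x$pt), "PTs, N =",
      x$N, ", target events =", x$drug_total, "\n")
  invisible(x)
}

#' Build a 2x2 contingency table from a cell and its margins
#'
#' Given the target-drug x target-term event count `a`, the target-drug
#' event total, the term event total and the grand total `N`, completes
#' the 2x2 table: `b = drug_total - a`, `c = term_total - a`,
#' `d = N - a - b - c`. Violated marginal constraints are a hard error
#' echoing all four inputs.
#'
#' @param a events with target drug and target term.
#' @param drug_total all target-drug events in the stratum.
#' @param term_total all target-term events in the stratum.
#' @param N grand total of (report, PT) events in the stratum.
#' @return object of class `contingency_table`: list `a`, `b`, `c`, `d`, `N`.
#' @export
make_table <- function(a, drug_total, term_total, N) {
  vals <- c(a = a, drug_total = drug_total, term_total = term_total, N = N)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals))) {
    abort_fs("counts must be non-negative integers: ",
             paste(names(vals), vals, sep = "=", collapse = ", "))
  }
  if (a > min(drug_total, term_total) || drug_total + term_total - a > N) {
    abort_fs("inconsistent margins: ",
             paste(names(vals), vals, sep = "=", collapse = ", "))
  }
  b <- drug_total - a
  cc <- term_total - a
  d <- N - a - b - cc
  structure(list(a = a, b = b, c = cc, d = d, N = N),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> a=%g b=%g c=%g d=%g (N=%g)\n",
              x$a, x$b, x$c, x$d, x$N))
  invisible(x)
}

#' Reconstruct a 2x2 table from published marginals and a printed ROR
#'
#' Validation utility inverting a published disproportionality row: given
#' `a`, the target-drug event total, the grand total `N` and the printed
#' point ROR (the anchor), solves `ROR = a*d/(b*c)` for the comparator
#' cell `c = round((N - drug_total) / (1 + anchor*(drug_total - a)/a))`
#' and completes the table. The recomputed ROR must round (2 dp) back to
#' the anchor, otherwise the row is irreconcilable and an error is
#' raised.
#'
#' @param a target cell count (>= 1).
#' @param drug_total target-drug event total.
#' @param N grand event total.
#' @param anchor printed ROR point value (> 0).
#' @return a `contingency_table`.
#' @export
reconstruct_table <- function(a, drug_total, N, anchor) {
  stopifnot(a >= 1, anchor > 0)
  b <- drug_total - a
  cc <- round((N - drug_total) / (1 + anchor * b / a))
  t <- make_table(a, drug_total, a + cc, N)
  ror <- t$a * t$d / (t$b * t$c)
  if (round(ror, 2) != round(anchor, 2)) {
    abort_fs(sprintf(
      "irreconcilable row: no integer c reproduces ROR %.2f (got %.2f at c=%d)",
      anchor, ror, as.integer(cc)))
  }
  t
}
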