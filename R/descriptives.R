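# Descriptive summaries of a report set: characteristics table (sex, age
# bands, reporter, countries, routes, outcomes, onset quartiles), annual
# report distribution and top-K term frequency tables.

age_band <- function(age) {
  cut_lab <- rep("UNK", length(age))
  ok <- !is.na(age)
  cut_lab[ok & age < 18] <- "<18"
  cut_lab[ok & age >= 18 & age < 45] <- "18-44"
  cut_lab[ok & age >= 45 & age < 65] <- "45-64"
  cut_lab[ok & age >= 65] <- ">=65"
  factor(cut_lab, levels = c("<18", "18-44", "45-64", ">=65", "UNK"))
}

count_block <- function(x, denom, top = NULL) {
  tab <- sort(table(x), decreasing = TRUE)
  out <- tibble::tibble(value = names(tab), n = as.integer(tab),
                        pct = round(100 * as.integer(tab) / denom, 2))
  if (!is.null(top)) out <- utils::head(out, top)
  out
}

#' Days from first suspect-drug therapy start to event onset
#'
#' For each report: `event_dt` minus the earliest therapy start date
#' among primary-suspect target drugs, in days. Requires full 8-digit
#' dates on both sides; a negative difference (event before start) is
#' treated as missing. Zero is a legal value (event on the start day).
#'
#' @param cases a `faers_cases` bundle.
#' @param target_ingredients normalized target ingredient labels.
#' @return named numeric vector (names = primaryid), `NA` where undefined.
#' @export
onset_days <- function(cases, target_ingredients) {
  stopifnot(inherits(cases, "faers_cases"))
  dd <- cases$drugs
  hit <- dd$role == "PS" & !is.na(dd$ingredient) &
    dd$ingredient %in% target_ingredients & is_date8(dd$start_dt)
  starts <- if (any(hit)) {
    dd[hit, ] |>
      dplyr::group_by(.data$primaryid) |>
      dplyr::summarise(start_dt = min(.data$start_dt), .groups = "drop")
  } else {
    tibble::tibble(primaryid = character(), start_dt = character())
  }
  cc <- dplyr::left_join(cases$cases, starts, by = "primaryid")
  days <- as.numeric(parse_date8(cc$event_dt) - parse_date8(cc$start_dt))
  days[!is.na(days) & days < 0] <- NA_real_
  stats::setNames(days, cc$primaryid)
}

#' Characteristics summary of a report set
#'
#' Table-1-style summary: counts and percentages for sex, age bands
#' (`<18`, `18-44`, `45-64`, `>=65`, unknown; left-closed boundaries),
#' reporter occupation, top-5 reporting countries, top-5 administration
#' routes, outcome codes, plus onset-time quartiles (median, Q1, Q3 in
#' days) when `target_ingredients` is given. Percentage denominators are
#' the number of reports; route and outcome blocks can sum away from 100
#' because a report may carry several entries.
#'
#' @param cases a `faers_cases` bundle (already restricted to the cohort
#'   of interest).
#' @param target_ingredients optional; enables the onset block.
#' @return list of tibbles (`sex`, `age`, `reporter`, `country`,
#'   `route`, `outcomes`) plus `onset` (named numeric: `median`, `q1`,
#'   `q3`, `n`) and `n_reports`.
#' @export
summarize_characteristics <- function(cases, target_ingredients = NULL) {
  stopifnot(inherits(cases, "faers_cases"))
  n <- nrow(cases$cases)
  if (n == 0) warning("empty cohort: all-zero summary")
  denom <- max(n, 1L)
  out <- list(
    n_reports = n,
    sex = count_block(factor(cases$cases$sex, levels = c("F", "M", "UNK")),
                      denom),
    age = count_block(age_band(cases$cases$age_years), denom),
    reporter = count_block(cases$cases$reporter, denom),
    country = count_block(cases$cases$country, denom, top = 5),
    route = count_block(cases$drugs$route, denom, top = 5),
    outcomes = count_block(cases$outcomes$outc_cod, denom)
  )
  if (!is.null(target_ingredients)) {
    d <- onset_days(cases, target_ingredients)
    d <- d[!is.na(d)]
    q <- if (length(d) > 0) {
      stats::quantile(d, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
    } else {
      c(NA_real_, NA_real_, NA_real_)
    }
    out$onset <- c(median = q[1], q1 = q[2], q3 = q[3], n = length(d))
  }
  out
}

#' Annual report counts
#'
#' One count per calendar year of the receipt date; reports whose year
#' cannot be parsed land in an `"UNK"` bucket. The counts sum to the
#' cohort size.
#'
#' @param cases a `faers_cases` bundle.
#' @return tibble with `year`, `n`, sorted by year (UNK last).
#' @export
annual_counts <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  if (nrow(cases$cases) == 0) return(tibble::tibble(year = character(),
                                                    n = integer()))
  tab <- table(cases$cases$year)
  out <- tibble::tibble(year = names(tab), n = as.integer(tab))
  out[order(out$year == "UNK", out$year), ]
}

#' Top-K terms by target event frequency
#'
#' Ranks terms of an [tabulate_events()] result by descending target
#' event count `a`, ties broken by term name. Percentages are relative
#' to the total target events over ALL terms at that level, so they are
#' invariant to `k`.
#'
#' @param counts an `event_counts` object.
#' @param k number of rows to keep (`k` larger than the number of terms
#'   returns all; `k <= 0` is an error).
#' @param level `"pt"` or `"soc"`.
#' @return tibble `term`, `a`, `pct`.
#' @export
top_terms <- function(counts, k = 50, level = c("pt", "soc")) {
  level <- match.arg(level)
  stopifnot(inherits(counts, "event_counts"))
  if (k <= 0) abort_fs("k must be positive")
  tab <- counts[[level]]
  total <- sum(tab$a)
  out <- tibble::tibble(term = tab$term, a = tab$a,
                        pct = if (total > 0) round(100 * tab$a / total, 2)
                              else rep(0, nrow(tab)))
  out <- out[order(-out$a, out$term), ]
  utils::head(out, k)
}
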