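# Published reference rows for the low-molecular-weight-heparin signal
# analysis, and the regression utility that revalidates the estimators
# against them.

#' Published LMWH disproportionality reference rows
#'
#' A fixture of published signal-detection results for low molecular
#' weight heparin: for each (stratum, term) row, the target event count
#' `a`, the stratum marginals (`drug_total` target events, `n_total`
#' grand events) and every printed statistic (ROR/PRR with 95% bounds,
#' Pearson chi-square, IC and IC025, EBGM and EBGM05). The overall
#' stratum has 61,949 target events among 52,373,206; the pregnancy
#' stratum 7,840 among 1,279,728. Only rows whose full 2x2 table is
#' exactly recoverable from these marginals plus the printed ROR (via
#' [reconstruct_table()]) are included.
#'
#' @return tibble of reference rows.
#' @export
reference_rows <- function() {
  path <- system.file("extdata", "lmwh_reference_rows.csv",
                      package = "faersignal", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Revalidate the estimators against the published reference rows
#'
#' For every row of [reference_rows()]: reconstructs the 2x2 table from
#' `a`, the stratum marginals and the printed ROR anchor, recomputes all
#' statistics with this package, and compares them with the printed
#' values -- point statistics, chi-square, IC, IC025, EBGM and EBGM05 at
#' 2-decimal rounding, interval bounds at 3 significant digits (published
#' interval bounds are known to wobble in the 4th-5th significant digit).
#'
#' @param rows reference rows; defaults to the shipped fixture.
#' @return tibble: one row per reference row with recomputed values and
#'   a logical `all_match`.
#' @export
validate_reference_rows <- function(rows = reference_rows()) {
  point_cols <- c("ror", "prr", "chi2", "ic", "ic025", "ebgm", "ebgm05")
  int_cols <- c("ror_lo", "ror_hi", "prr_lo", "prr_hi")
  out <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    t <- reconstruct_table(r$a, r$drug_total, r$n_total, r$ror)
    s <- signal_stats(t)
    ok_point <- vapply(point_cols,
                       function(cl) round(s[[cl]], 2) == r[[cl]], TRUE)
    ok_int <- vapply(int_cols,
                     function(cl) signif(s[[cl]], 3) == signif(r[[cl]], 3),
                     TRUE)
    tibble::tibble(stratum = r$stratum, term = r$term,
                   a = r$a, c = t$c, s,
                   all_match = all(ok_point) && all(ok_int))
  })
  dplyr::bind_rows(out)
}
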