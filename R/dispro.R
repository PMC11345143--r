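# The four disproportionality estimators (ROR, PRR + Pearson chi-square,
# BCPNN information component, observed/expected EBGM ratio) with 95%
# interval bounds, the combined six-part signal criterion, and signal
# ranking.
#
# Conventions: z = 1.96 for all 95% bounds; ROR/PRR/EBGM intervals on
# the natural-log scale, the information component on base 2. Any zero
# cell makes the statistics undefined (NA) -- no continuity correction --
# and an undefined statistic can never satisfy its criterion.

#' BCPNN prior constants
#'
#' Prior constants for the Bayesian confidence propagation neural
#' network credibility bound: `gamma11 = alpha1 = beta1 = 1`,
#' `alpha = beta = 2`; the joint prior count `gamma` is recomputed per
#' table as `gamma11*(N+alpha)*(N+beta) / ((a+b+alpha1)*(a+c+beta1))`.
#'
#' @param gamma11,alpha1,beta1,alpha,beta positive prior constants.
#' @return object of class `bcpnn_prior`.
#' @export
bcpnn_prior <- function(gamma11 = 1, alpha1 = 1, beta1 = 1,
                        alpha = 2, beta = 2) {
  vals <- c(gamma11 = gamma11, alpha1 = alpha1, beta1 = beta1,
            alpha = alpha, beta = beta)
  stopifnot(all(vals > 0))
  structure(as.list(vals), class = "bcpnn_prior")
}

# Vectorized core: all statistics from the four cells. Returns a tibble;
# zero cells give NA everywhere (chi2 included, since its criterion is
# only meaningful alongside the ratios).
dispro_all <- function(a, b, c, d, prior = bcpnn_prior()) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  nax <- function(x) ifelse(ok, x, NA_real_)

  se_or <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ror <- a * d / (b * c)
  prr <- (a / (a + b)) / (c / (c + d))
  se_prr <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  chi2 <- N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  ebgm <- a * N / ((a + b) * (a + c))
  ic <- log2(ebgm)

  g11 <- prior$gamma11; a1 <- prior$alpha1; b1 <- prior$beta1
  al <- prior$alpha; be <- prior$beta
  gam <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  e_ic <- log2((a + g11) * (N + al) * (N + be) /
                 ((N + gam) * (a + b + a1) * (a + c + b1)))
  v_ic <- (1 / log(2))^2 * (
    (N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
      (N - (a + b) + al - a1) / ((a + b + a1) * (1 + N + al)) +
      (N - (a + c) + be - b1) / ((a + c + b1) * (1 + N + be)))

  tibble::tibble(
    n = a,
    ror = nax(ror),
    ror_lo = nax(exp(log(ror) - 1.96 * se_or)),
    ror_hi = nax(exp(log(ror) + 1.96 * se_or)),
    prr = nax(prr),
    prr_lo = nax(exp(log(prr) - 1.96 * se_prr)),
    prr_hi = nax(exp(log(prr) + 1.96 * se_prr)),
    chi2 = nax(chi2),
    ic = nax(ic),
    ic025 = nax(e_ic - 2 * sqrt(v_ic)),
    ebgm = nax(ebgm),
    ebgm05 = nax(exp(log(ebgm) - 1.96 * se_or))
  )
}

stats_row <- function(t, prior = bcpnn_prior()) {
  stopifnot(inherits(t, "contingency_table"))
  dispro_all(t$a, t$b, t$c, t$d, prior)
}

#' Reporting odds ratio with 95% confidence bounds
#'
#' `ROR = a*d/(b*c)` with lognormal bounds
#' `exp(ln ROR -/+ 1.96*sqrt(1/a+1/b+1/c+1/d))`. Undefined (NA) when any
#' cell is zero.
#'
#' @param t a `contingency_table`.
#' @return named numeric: `ror`, `ror_lo`, `ror_hi`.
#' @export
ror_stats <- function(t) {
  s <- stats_row(t)
  c(ror = s$ror, ror_lo = s$ror_lo, ror_hi = s$ror_hi)
}

#' Proportional reporting ratio, bounds and Pearson chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with lognormal bounds, and the Pearson
#' chi-square `N*(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))` without Yates
#' continuity correction.
#'
#' @param t a `contingency_table`.
#' @return named numeric: `prr`, `prr_lo`, `prr_hi`, `chi2`.
#' @export
prr_stats <- function(t) {
  s <- stats_row(t)
  c(prr = s$prr, prr_lo = s$prr_lo, prr_hi = s$prr_hi, chi2 = s$chi2)
}

#' BCPNN information component and lower credibility bound
#'
#' The point information component is the unshrunk
#' `IC = log2(a*N / ((a+b)*(a+c)))`; the lower bound `IC025` is the Bate
#' posterior expectation minus two posterior standard deviations under
#' the [bcpnn_prior()] constants ("IC - 2SD").
#'
#' @param t a `contingency_table`.
#' @param prior a [bcpnn_prior()].
#' @return named numeric: `ic`, `ic025`.
#' @export
bcpnn_stats <- function(t, prior = bcpnn_prior()) {
  s <- stats_row(t, prior)
  c(ic = s$ic, ic025 = s$ic025)
}

#' Observed/expected EBGM ratio and lower 95% bound
#'
#' `EBGM = a*N / ((a+b)*(a+c))` -- the observed-to-expected reporting
#' ratio, labelled EBGM as is conventional in signal tables -- with
#' `EBGM05 = exp(ln EBGM - 1.96*sqrt(1/a+1/b+1/c+1/d))`. No
#' gamma-mixture (MGPS) shrinkage is applied; see the methods vignette.
#'
#' @param t a `contingency_table`.
#' @return named numeric: `ebgm`, `ebgm05`.
#' @export
ebgm_stats <- function(t) {
  s <- stats_row(t)
  c(ebgm = s$ebgm, ebgm05 = s$ebgm05)
}

#' All disproportionality statistics for one table
#'
#' @param t a `contingency_table`.
#' @param prior a [bcpnn_prior()].
#' @return one-row tibble with `n`, `ror` (+bounds), `prr` (+bounds),
#'   `chi2`, `ic`, `ic025`, `ebgm`, `ebgm05`.
#' @export
signal_stats <- function(t, prior = bcpnn_prior()) {
  stats_row(t, prior)
}

#' Combined signal-detection criteria
#'
#' The six-part conjunctive criterion: `a >= min_a`, lower ROR bound
#' `> ror_lo_gt`, `PRR >= prr_ge`, `chi-square >= chi2_ge`,
#' `IC025 > ic025_gt`, `EBGM05 > ebgm05_gt`.
#'
#' @param min_a,ror_lo_gt,prr_ge,chi2_ge,ic025_gt,ebgm05_gt thresholds.
#' @return object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_a = 3, ror_lo_gt = 1, prr_ge = 2,
                            chi2_ge = 4, ic025_gt = 0, ebgm05_gt = 2) {
  structure(list(min_a = min_a, ror_lo_gt = ror_lo_gt, prr_ge = prr_ge,
                 chi2_ge = chi2_ge, ic025_gt = ic025_gt,
                 ebgm05_gt = ebgm05_gt),
            class = "signal_criteria")
}

#' Evaluate the combined signal criterion
#'
#' Applies [signal_criteria()] to a statistics row (or several). An
#' undefined (NA) statistic fails its flag; the combined flag is the
#' conjunction of all six.
#'
#' @param stats tibble as returned by [signal_stats()] / [dispro_all()].
#' @param criteria a [signal_criteria()].
#' @return `stats` with logical columns `flag_n`, `flag_ror`,
#'   `flag_prr`, `flag_chi2`, `flag_ic`, `flag_ebgm` and `signal`.
#' @export
evaluate_criteria <- function(stats, criteria = signal_criteria()) {
  na_false <- function(x) !is.na(x) & x
  stats$flag_n <- na_false(stats$n >= criteria$min_a)
  stats$flag_ror <- na_false(stats$ror_lo > criteria$ror_lo_gt)
  stats$flag_prr <- na_false(stats$prr >= criteria$prr_ge)
  stats$flag_chi2 <- na_false(stats$chi2 >= criteria$chi2_ge)
  stats$flag_ic <- na_false(stats$ic025 > criteria$ic025_gt)
  stats$flag_ebgm <- na_false(stats$ebgm05 > criteria$ebgm05_gt)
  stats$signal <- stats$flag_n & stats$flag_ror & stats$flag_prr &
    stats$flag_chi2 & stats$flag_ic & stats$flag_ebgm
  stats
}

#' Per-term signal table for a stratum
#'
#' Builds the 2x2 table for every term at the requested level from
#' tabulated event counts, computes all four estimators with bounds,
#' and evaluates the combined criterion.
#'
#' @param counts an `event_counts` object from [tabulate_events()].
#' @param level `"pt"` or `"soc"`.
#' @param criteria a [signal_criteria()].
#' @param prior a [bcpnn_prior()].
#' @return tibble with term identification, all statistics, per-criterion
#'   flags and the combined `signal` flag, one row per term.
#' @export
signal_table <- function(counts, level = c("pt", "soc"),
                         criteria = signal_criteria(),
                         prior = bcpnn_prior()) {
  level <- match.arg(level)
  stopifnot(inherits(counts, "event_counts"))
  tab <- counts[[level]]
  if (nrow(tab) == 0) {
    out <- evaluate_criteria(dispro_all(numeric(0), numeric(0),
                                        numeric(0), numeric(0), prior),
                             criteria)
    return(tibble::tibble(term = character(0), level = character(0), out))
  }
  a <- tab$a
  b <- counts$drug_total - a
  cc <- tab$term_total - a
  d <- counts$N - a - b - cc
  stats <- dispro_all(a, b, cc, d, prior)
  stats <- evaluate_criteria(stats, criteria)
  id <- if (level == "pt") {
    tibble::tibble(term = tab$term, level = "PT", pt_code = tab$pt_code,
                   soc = tab$soc)
  } else {
    tibble::tibble(term = tab$term, level = "SOC")
  }
  dplyr::bind_cols(id, stats)
}

#' Rank detected signals
#'
#' Keeps rows with the combined flag and orders them by descending ROR,
#' ties broken by descending `n` then term name. `top_k` limits the
#' output.
#'
#' @param stats_tbl tibble from [signal_table()] (or any tibble with
#'   `signal`, `ror`, `n`, `term`).
#' @param top_k optional row limit.
#' @return ordered tibble of signals.
#' @export
rank_signals <- function(stats_tbl, top_k = NULL) {
  out <- stats_tbl[!is.na(stats_tbl$signal) & stats_tbl$signal, ]
  out <- out[order(-out$ror, -out$n, out$term), ]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}
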