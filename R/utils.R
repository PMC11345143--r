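# Internal helpers shared across modules.

#' Fold a free-text name for dictionary lookup
#'
#' Lowercases, replaces every non-alphanumeric run with a single space and
#' trims. This is the only normalization applied to drug names and route
#' labels: deterministic and auditable, no fuzzy matching.
#'
#' @param x character vector.
#' @return folded character vector.
#' @keywords internal
fold_name <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

# TRUE where x is a full 8-digit YYYYMMDD date string.
is_date8 <- function(x) {
  !is.na(x) & grepl("^[0-9]{8}$", x)
}

# 8-digit date string -> Date; anything else (partial dates included) -> NA.
parse_date8 <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- is_date8(x)
  if (any(ok)) {
    d <- as.Date(x[ok], format = "%Y%m%d")
    out[ok] <- d
  }
  out
}

# Year prefix of a (possibly partial) FAERS date; "UNK" when unparseable.
# Partial 4/6-digit dates still carry a usable year.
date_year <- function(x) {
  x <- as.character(x)
  ok <- !is.na(x) & grepl("^(19|20)[0-9]{2}", x)
  out <- rep("UNK", length(x))
  out[ok] <- substr(x[ok], 1, 4)
  out
}

# Coerce to integer-valued numeric, NA on failure.
as_num <- function(x) suppressWarnings(as.numeric(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() without the call, consistent error style
abort_fs <- function(...) stop(..., call. = FALSE)
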