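#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Logit and inverse-logit
#'
#' Thin wrappers over [stats::qlogis()] and [stats::plogis()], exported because
#' trend extrapolation is phrased on the log-odds scale throughout.
#'
#' @param p probability in (0, 1).
#' @param x log-odds.
#' @return `logit()` returns log-odds; `invlogit()` returns a probability.
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
invlogit <- function(x) stats::plogis(x)

## Parse "YYYY-MM-DD" strings strictly; returns Date with NA for bad input.
parse_iso_date <- function(x) {
  x <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x) & !is.na(x)
  out <- rep(as.Date(NA), length(x))
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

## Strict integer parse; NA when not a plain (optionally signed) integer.
parse_integer_strict <- function(x) {
  x <- trimws(as.character(x))
  ok <- grepl("^[+-]?\\d+$", x) & !is.na(x)
  out <- rep(NA_real_, length(x))
  out[ok] <- as.numeric(x[ok])
  out
}

## Lenient numeric parse (decimal allowed); NA when not numeric.
parse_numeric <- function(x) {
  suppressWarnings(as.numeric(as.character(x)))
}

is_answered <- function(x) !is.na(x) & nzchar(trimws(as.character(x)))

## Largest-remainder (Hamilton) apportionment of an integer total across
## weights; deterministic tie-break by index order.
apportion_integer <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0), sum(weights) > 0)
  q <- total * weights / sum(weights)
  f <- floor(q)
  r <- as.integer(round(total - sum(f)))
  if (r > 0) {
    idx <- order(q - f, seq_along(q), decreasing = c(TRUE, FALSE), method = "radix")
    f[idx[seq_len(r)]] <- f[idx[seq_len(r)]] + 1
  }
  as.integer(f)
}
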