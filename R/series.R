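# Series containers. A binary_series is the symbolic object every estimator
# consumes: an integer vector over {0, 1} (0 = down, 1 = up) carrying a strictly
# consecutive monthly calendar. A monthly_series is its continuous precursor.

#' Construct a binary symbolic series
#'
#' @param symbols integer, numeric or logical vector of symbols; every element
#'   must be 0 (down) or 1 (up).
#' @param start first calendar month, `"YYYY-MM"`.
#' @param id optional label (state code, variable name).
#' @return a `binary_series`: integer vector with attributes `months` and `id`.
#' @export
binary_series <- function(symbols, start = "1999-01", id = NULL) {
  symbols <- as.integer(symbols)
  if (length(symbols) < 2L) stop("a binary series needs length >= 2")
  if (anyNA(symbols) || !all(symbols %in% c(0L, 1L))) {
    stop("symbols must all be 0 (down) or 1 (up)")
  }
  structure(symbols,
            months = month_seq(start, length(symbols)),
            id = id %||% NA_character_,
            class = "binary_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.binary_series <- function(x, ...) {
  m <- attr(x, "months")
  cat(sprintf("<binary_series '%s'> %d months %s..%s, %d up / %d down\n",
              attr(x, "id"), length(x), m[1], m[length(m)],
              sum(x == 1L), sum(x == 0L)))
  invisible(x)
}

#' Months covered by a series
#'
#' @param x a `binary_series` or `monthly_series`.
#' @return character vector of `"YYYY-MM"` labels.
#' @export
series_months <- function(x) attr(x, "months")

#' Construct a continuous monthly series
#'
#' @param values numeric vector, one value per month.
#' @param start first calendar month, `"YYYY-MM"`.
#' @param id optional unit label.
#' @param kind one of `"background_checks"`, `"media_count"`, `"residual"` or
#'   `"raw"`; [seasonal_adjust_detrend()] produces `"residual"`.
#' @return a `monthly_series`: numeric vector with attributes `months`, `id`,
#'   `kind`.
#' @export
monthly_series <- function(values, start = "1999-01", id = NULL, kind = "raw") {
  values <- as.numeric(values)
  if (anyNA(values)) stop("monthly series values must not be NA")
  kind <- match.arg(kind, c("raw", "background_checks", "media_count", "residual"))
  structure(values,
            months = month_seq(start, length(values)),
            id = id %||% NA_character_,
            kind = kind,
            class = "monthly_series")
}

#' @export
print.monthly_series <- function(x, ...) {
  m <- attr(x, "months")
  cat(sprintf("<monthly_series '%s' kind=%s> %d months %s..%s\n",
              attr(x, "id"), attr(x, "kind"), length(x), m[1], m[length(m)]))
  invisible(x)
}

#' Restrict a series to a month window
#'
#' @param x a `binary_series` or `monthly_series`.
#' @param window `c(start, end)` months, inclusive.
#' @return a series of the same class covering exactly the window.
#' @export
clip_months <- function(x, window) {
  m <- series_months(x)
  want <- month_seq(window[1], window_length(window))
  if (!all(want %in% m)) {
    stop("series '", attr(x, "id"), "' does not cover window month(s): ",
         paste(utils::head(setdiff(want, m), 3), collapse = ", "))
  }
  keep <- match(want, m)
  if (inherits(x, "binary_series")) {
    binary_series(unclass(x)[keep], start = window[1], id = attr(x, "id"))
  } else {
    monthly_series(unclass(x)[keep], start = window[1], id = attr(x, "id"),
                   kind = attr(x, "kind"))
  }
}

# Stop unless all series share one calendar. Returns the common months.
check_aligned <- function(...) {
  series <- list(...)
  series <- series[!vapply(series, is.null, logical(1))]
  months <- lapply(series, series_months)
  first <- months[[1]]
  for (m in months[-1]) {
    if (length(m) != length(first) || !all(m == first)) {
      stop("series are not aligned: differing calendars or lengths")
    }
  }
  first
}
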