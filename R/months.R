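# Calendar-month arithmetic. Months are written "YYYY-MM" on every external
# surface and handled internally as integer month ids (year * 12 + month - 1),
# so gaps and alignment reduce to integer arithmetic.

#' Convert "YYYY-MM" labels to integer month ids
#'
#' The id of month m in year y is `12 * y + m - 1`; consecutive calendar
#' months differ by exactly one.
#'
#' @param ym character vector of months in `"YYYY-MM"` form.
#' @return integer vector of month ids.
#' @export
month_id <- function(ym) {
  ok <- grepl("^[0-9]{4}-(0[1-9]|1[0-2])$", ym)
  if (!all(ok)) {
    stop("malformed month label(s): ", paste(unique(ym[!ok]), collapse = ", "))
  }
  12L * as.integer(substr(ym, 1, 4)) + as.integer(substr(ym, 6, 7)) - 1L
}

#' Convert integer month ids back to "YYYY-MM" labels
#'
#' @param id integer vector of month ids (see [month_id()]).
#' @return character vector of `"YYYY-MM"` labels.
#' @export
month_label <- function(id) {
  id <- as.integer(id)
  sprintf("%04d-%02d", id %/% 12L, id %% 12L + 1L)
}

#' Sequence of consecutive calendar months
#'
#' @param start first month, `"YYYY-MM"`.
#' @param length number of months.
#' @return character vector of `length` consecutive month labels.
#' @export
month_seq <- function(start, length) {
  month_label(month_id(start) + seq_len(length) - 1L)
}

#' Number of months spanned by a window, inclusive of both ends
#'
#' @param window character vector of two months, `c(start, end)`.
#' @return integer month count.
#' @export
window_length <- function(window) {
  n <- month_id(window[2]) - month_id(window[1]) + 1L
  if (n < 1L) stop("window end precedes window start")
  n
}

# month-of-year (1..12) for a vector of month labels
month_of_year <- function(ym) month_id(ym) %% 12L + 1L
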