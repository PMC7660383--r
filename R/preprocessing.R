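# From raw monthly counts and event lists to the binary symbolic series the
# estimators consume: seasonal adjustment + detrending, sign and median
# symbolization, mode aggregation, and event-occurrence encoding.

#' Seasonally adjust and linearly detrend a monthly series
#'
#' Classical decomposition: the series is regressed by ordinary least squares
#' on an intercept, a linear time term and month-of-year indicators, and the
#' residual is returned. The residual has exactly zero sample mean and zero
#' month-of-year means, and any input of the form line + 12-month-periodic
#' profile is reproduced exactly (residual 0 to machine precision). This
#' replaces the ARIMA-model-based seasonal adjustment used on the original
#' background-check data, which is not reproducible from its description; only
#' the sign of the anomaly survives the downstream symbolization.
#'
#' @param series a [monthly_series()] of length >= 24 (two full seasonal
#'   cycles).
#' @return a [monthly_series()] of kind `"residual"` on the same calendar.
#' @export
seasonal_adjust_detrend <- function(series) {
  stopifnot(inherits(series, "monthly_series"))
  T <- length(series)
  if (T < 24L) stop("need at least 24 months (two seasonal cycles), got ", T)
  y <- as.numeric(series)
  t <- seq_len(T)
  moy <- factor(month_of_year(series_months(series)), levels = 1:12)
  r <- stats::residuals(stats::lm(y ~ t + moy))
  monthly_series(as.numeric(r), start = series_months(series)[1],
                 id = attr(series, "id"), kind = "residual")
}

#' Symbolize a residual series by sign
#'
#' Positive values map to up (1); negative or zero values map to down (0).
#'
#' @param residual a [monthly_series()] of kind `"residual"`.
#' @return a [binary_series()].
#' @export
symbolize_sign <- function(residual) {
  stopifnot(inherits(residual, "monthly_series"))
  if (!identical(attr(residual, "kind"), "residual")) {
    stop("symbolize_sign expects a seasonally adjusted residual series; ",
         "run seasonal_adjust_detrend() first")
  }
  binary_series(as.integer(as.numeric(residual) > 0),
                start = series_months(residual)[1], id = attr(residual, "id"))
}

#' Symbolize a monthly series against its median
#'
#' Values strictly greater than the sample median of the whole series map to
#' up (1); values less than or equal to the median map to down (0). At most
#' `floor(T/2)` months can map to up.
#'
#' @param series a [monthly_series()].
#' @return a [binary_series()].
#' @export
symbolize_median <- function(series) {
  stopifnot(inherits(series, "monthly_series"))
  med <- stats::median(as.numeric(series))
  binary_series(as.integer(as.numeric(series) > med),
                start = series_months(series)[1], id = attr(series, "id"))
}

#' Per-month majority symbol across binary series
#'
#' The aggregate at each month is the modal symbol across the input series
#' (newspapers, neighboring states). Ties — possible only for even list sizes —
#' resolve to down (0) with a warning, consistent with the conservative
#' down-convention for zeros and median ties.
#'
#' @param series_list non-empty list of aligned [binary_series()].
#' @param id label for the aggregate series.
#' @return a [binary_series()].
#' @export
aggregate_mode <- function(series_list, id = "mode") {
  if (!length(series_list)) stop("aggregate_mode needs at least one series")
  do.call(check_aligned, series_list)
  m <- vapply(series_list, unclass, integer(length(series_list[[1]])))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  ups <- rowSums(m)
  k <- length(series_list)
  if (k %% 2L == 0L && any(ups * 2L == k)) {
    warning(sum(ups * 2L == k), " mode tie(s) resolved to down", call. = FALSE)
  }
  binary_series(as.integer(ups * 2L > k),
                start = series_months(series_list[[1]])[1], id = id)
}

#' Resolve state identifiers to 2-letter codes
#'
#' Accepts 2-letter codes or full names of the 50 states and DC
#' (case-insensitive).
#'
#' @param x character vector of state identifiers.
#' @return character vector of 2-letter codes.
#' @export
resolve_state <- function(x) {
  lut <- stats::setNames(c(datasets::state.abb, "DC",
                           datasets::state.abb, "DC"),
                         toupper(c(datasets::state.abb, "DC",
                                   datasets::state.name,
                                   "District of Columbia")))
  out <- lut[toupper(trimws(x))]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unresolvable state identifier(s): ", paste(bad, collapse = ", "))
  }
  unname(out)
}

#' Encode a mass-shooting event list as a monthly binary series
#'
#' A month maps to up (1) when at least one retained event falls in it; events
#' sharing a month collapse to a single up. Scopes: `"national"` retains every
#' event; `"in_state"` retains events in `state`; `"elsewhere"` retains events
#' in any unit other than `state` — including units excluded from the analysis
#' as effects (e.g. Connecticut, Hawaii, DC).
#'
#' @param events data frame with columns `name`, `state`, `date` (`Date` or
#'   ISO string).
#' @param window `c(start, end)` months; events outside it are dropped.
#' @param scope `"national"`, `"in_state"` or `"elsewhere"`.
#' @param state focal 2-letter state code, required for the state scopes.
#' @param id label for the output series (defaults to the scope).
#' @param resolve validate state identifiers against the 50 states + DC via
#'   [resolve_state()]; set `FALSE` for synthetic unit codes, which are then
#'   matched verbatim.
#' @return a [binary_series()] spanning the window.
#' @export
events_to_binary <- function(events, window = c("1999-01", "2017-12"),
                             scope = c("national", "in_state", "elsewhere"),
                             state = NULL, id = NULL, resolve = TRUE) {
  scope <- match.arg(scope)
  codes <- if (resolve) resolve_state(events$state) else
    as.character(events$state)
  if (scope != "national") {
    if (is.null(state)) stop("scope '", scope, "' needs a focal state")
    if (resolve) state <- resolve_state(state)
  }
  keep <- switch(scope,
                 national = rep(TRUE, length(codes)),
                 in_state = codes == state,
                 elsewhere = codes != state)
  dates <- as.Date(events$date)
  if (anyNA(dates)) stop("unparseable event date(s)")
  ev_month <- month_id(format(dates[keep], "%Y-%m"))
  ids <- month_id(window[1]) + seq_len(window_length(window)) - 1L
  ev_month <- ev_month[ev_month >= ids[1] & ev_month <= ids[length(ids)]]
  binary_series(as.integer(ids %in% ev_month), start = window[1],
                id = id %||% switch(scope,
                                    national = "MS",
                                    in_state = paste0("MSst_", state),
                                    elsewhere = paste0("MSe_", state)))
}
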