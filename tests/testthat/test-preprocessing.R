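# Seasonal adjustment, symbolization rules, mode aggregation, event encoding.

test_that("seasonal_adjust_detrend removes trend and 12-month seasonality exactly", {
  T <- 96
  t <- seq_len(T)
  line <- monthly_series(3.2 + 0.7 * t, "1999-01", id = "line")
  expect_lt(max(abs(seasonal_adjust_detrend(line))), 1e-9)
  seas <- monthly_series(3.2 + 0.7 * t + 5 * sin(2 * pi * t / 12), "1999-01")
  expect_lt(max(abs(seasonal_adjust_detrend(seas))), 1e-9)
  expect_error(seasonal_adjust_detrend(monthly_series(rnorm(20), "1999-01")),
               "24 months")
})

test_that("residuals have zero mean and zero month-of-year means", {
  set.seed(13)
  x <- monthly_series(100 + 0.5 * seq_len(90) + rnorm(90, sd = 10), "1999-04")
  r <- seasonal_adjust_detrend(x)
  expect_equal(attr(r, "kind"), "residual")
  expect_lt(abs(mean(r)), 1e-9)
  moy <- month_id(series_months(r)) %% 12
  expect_lt(max(abs(tapply(as.numeric(r), moy, mean))), 1e-9)
})

test_that("sign symbolization: positive up, zero and negative down", {
  r <- monthly_series(c(0.5, -0.2, 0.0), "1999-01", kind = "residual")
  # length-3 series is fine for symbolization even if too short to adjust
  expect_equal(as.integer(symbolize_sign(r)), c(1L, 0L, 0L))
  allpos <- monthly_series(rep(2.5, 30), "1999-01", kind = "residual")
  expect_true(all(symbolize_sign(allpos) == 1L))
  set.seed(3)
  v <- rnorm(40)
  v[v == 0] <- 1
  a <- symbolize_sign(monthly_series(v, "1999-01", kind = "residual"))
  b <- symbolize_sign(monthly_series(-v, "1999-01", kind = "residual"))
  expect_equal(as.integer(b), 1L - as.integer(a))
  expect_error(symbolize_sign(monthly_series(v, "1999-01", kind = "raw")),
               "residual")
})

test_that("median symbolization: strict-greater rule, ties down", {
  expect_equal(as.integer(symbolize_median(monthly_series(1:5, "1999-01"))),
               c(0L, 0L, 0L, 1L, 1L))
  expect_true(all(symbolize_median(monthly_series(rep(7, 12), "1999-01")) == 0L))
  set.seed(29)
  for (i in 1:20) {
    T <- sample(3:60, 1)
    v <- sample(0:5, T, replace = TRUE)
    expect_lte(sum(symbolize_median(monthly_series(v, "1999-01")) == 1L),
               floor(T / 2))
  }
})

test_that("mode aggregation: majority rule, tie handling, invariances", {
  a <- bs(c(1, 1, 0, 0)); b <- bs(c(1, 0, 0, 1)); c_ <- bs(c(0, 1, 0, 1))
  expect_equal(as.integer(aggregate_mode(list(a))), as.integer(a))
  expect_equal(as.integer(aggregate_mode(list(a, b, c_))), c(1L, 1L, 0L, 1L))
  five <- c(replicate(3, bs(c(1, 1)), simplify = FALSE),
            replicate(2, bs(c(0, 0)), simplify = FALSE))
  expect_true(all(aggregate_mode(five) == 1L))
  # identical copies and order changes leave the mode unchanged
  expect_equal(as.integer(aggregate_mode(list(a, a, a))), as.integer(a))
  expect_equal(as.integer(aggregate_mode(list(c_, a, b))),
               as.integer(aggregate_mode(list(a, b, c_))))
  expect_warning(m <- aggregate_mode(list(a, bs(c(0, 0, 1, 1)))), "tie")
  expect_equal(as.integer(m), c(0L, 0L, 0L, 0L))
  expect_error(aggregate_mode(list()), "at least one")
})

test_that("event encoding: scopes, window, packaged table", {
  empty <- data.frame(name = character(0), state = character(0),
                      date = as.Date(character(0)))
  expect_true(all(events_to_binary(empty, c("1999-01", "2000-12")) == 0L))
  ev <- packaged_events()
  ms <- events_to_binary(ev, c("1999-01", "2017-12"), "national")
  expect_equal(length(ms), 228L)
  expect_equal(as.integer(ms)[match("1999-04", series_months(ms))], 1L)
  ca <- events_to_binary(ev, c("1999-01", "2017-12"), "in_state", "CA")
  expect_equal(sum(ca), 11L)
  # same-month events collapse to a single up
  two <- data.frame(name = c("a", "b"), state = c("TX", "TX"),
                    date = as.Date(c("1999-03-01", "1999-03-20")))
  expect_equal(sum(events_to_binary(two, c("1999-01", "1999-12"),
                                    "in_state", "TX")), 1L)
  expect_error(
    events_to_binary(data.frame(name = "x", state = "ZZ",
                                date = as.Date("2000-01-01")),
                     c("1999-01", "2000-12")),
    "ZZ")
  # full names resolve too
  expect_equal(resolve_state(c("california", "DC", "New Mexico")),
               c("CA", "DC", "NM"))
})

test_that("national series is the elementwise OR of all per-unit series", {
  ev <- packaged_events()
  w <- c("1999-01", "2017-12")
  nat <- as.integer(events_to_binary(ev, w, "national"))
  units <- unique(ev$state)
  per_unit <- sapply(units, function(s)
    as.integer(events_to_binary(ev, w, "in_state", s)))
  expect_equal(nat, as.integer(rowSums(per_unit) > 0))
  # and MSe is determined purely by out-of-state occurrence
  mse_ca <- as.integer(events_to_binary(ev, w, "elsewhere", "CA"))
  others <- setdiff(units, "CA")
  expect_equal(mse_ca,
               as.integer(rowSums(per_unit[, others]) > 0))
})
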