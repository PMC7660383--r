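# Seeded synthetic-data generators. They state the world the tests assume:
# 228-month series (the 1999-01..2017-12 study window), ~48 geographic units,
# planted lag-1 causal couplings of tunable strength, a persistent-driver
# confounder chain, a bimodal law-restrictiveness distribution, populations
# spanning two orders of magnitude, and centroids on a jittered plane grid.

#' Coupled binary pair with tunable lag-1 coupling
#'
#' The cause is an iid fair binary process; the effect copies the cause's
#' previous symbol with probability `coupling` and is otherwise a fair coin,
#' so the true transfer entropy is available in closed form from
#' [coupled_pmf()] (0 bits at `coupling = 0`, 1 bit at `coupling = 1`).
#'
#' @param T series length in months (study default 228).
#' @param coupling copy probability in `[0, 1]`.
#' @param seed integer seed.
#' @param start first month.
#' @return list with `cause` and `effect` [binary_series()].
#' @export
gen_coupled_binary <- function(T = 228, coupling = 0.5, seed = 1,
                               start = "1999-01") {
  if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
  set.seed(seed)
  x <- stats::rbinom(T, 1L, 0.5)
  y <- integer(T)
  y[1] <- stats::rbinom(1, 1L, 0.5)
  copy <- stats::runif(T - 1) < coupling
  noise <- stats::rbinom(T - 1, 1L, 0.5)
  y[-1] <- ifelse(copy, x[-T], noise)
  list(cause = binary_series(x, start, id = "X"),
       effect = binary_series(y, start, id = "Y"))
}

#' Exact stationary pmf of the coupled binary pair
#'
#' Joint distribution of `(Y(t+1), Y(t), X(t))` under the
#' [gen_coupled_binary()] kernel: `X` iid fair, `Y(t)` independent of `X(t)`,
#' `P(Y(t+1) = X(t)) = coupling + (1 - coupling)/2`.
#'
#' @param coupling copy probability in `[0, 1]`.
#' @return pmf data frame for [te_from_pmf()].
#' @export
coupled_pmf <- function(coupling = 0.5) {
  g <- expand.grid(y_next = 0:1, y_now = 0:1, x_now = 0:1)
  p_copy <- coupling + (1 - coupling) / 2
  g$prob <- 0.25 * ifelse(g$y_next == g$x_now, p_copy, 1 - p_copy)
  g
}

#' Confounder chain x -> z -> y with a persistent driver
#'
#' Generates the mediated chain `z(t+1) = x(t)`, `y(t+1) = z(t)` driven by a
#' sticky binary Markov chain `x` with `P(x(t+1) = x(t)) = persistence`. With
#' a persistent driver the pairwise transfer entropy from x to y is positive
#' (x(t) is correlated with x(t-1) = y(t+1)) while the conditional transfer
#' entropy given z is exactly zero — the textbook spurious indirect coupling
#' that conditioning removes. An iid driver (`persistence = 0.5`) would make
#' both quantities zero at lag 1, which is why the default is 0.9.
#'
#' @param T series length.
#' @param seed integer seed.
#' @param persistence `P(x(t+1) = x(t))`, in `(0, 1)`.
#' @param start first month.
#' @return list with `x`, `z`, `y` [binary_series()].
#' @export
gen_confounded_triplet <- function(T = 228, seed = 1, persistence = 0.9,
                                   start = "1999-01") {
  if (persistence <= 0 || persistence >= 1) stop("persistence must be in (0, 1)")
  set.seed(seed)
  x <- integer(T + 2L)
  x[1] <- stats::rbinom(1, 1L, 0.5)
  stay <- stats::runif(T + 1L) < persistence
  for (t in seq_len(T + 1L)) x[t + 1L] <- if (stay[t]) x[t] else 1L - x[t]
  # z lags x by one, y lags z by one; drop burn-in so all have length T
  z <- x[seq_len(T) + 1L]
  y <- x[seq_len(T)]
  xx <- x[seq_len(T) + 2L]
  list(x = binary_series(xx, start, id = "X"),
       z = binary_series(z, start, id = "Z"),
       y = binary_series(y, start, id = "Y"))
}

#' Exact stationary pmf of the confounder chain
#'
#' Joint distribution of `(Y(t+1), Y(t), X(t), Z(t))` under the
#' [gen_confounded_triplet()] kernel. Writing `A` for the persistence kernel,
#' the tuple equals `(x(t-1), x(t-2), x(t), x(t-1))`, so `Z(t) = Y(t+1)`
#' deterministically and the chain factorizes through `A`.
#'
#' @param persistence `P(x(t+1) = x(t))`.
#' @param include_z keep the conditioning variable (drop it to obtain the
#'   pairwise pmf for plain transfer entropy).
#' @return pmf data frame for [te_from_pmf()].
#' @export
confounded_pmf <- function(persistence = 0.9, include_z = TRUE) {
  A <- function(from, to) ifelse(from == to, persistence, 1 - persistence)
  g <- expand.grid(y_next = 0:1, y_now = 0:1, x_now = 0:1, z = 0:1)
  g$prob <- ifelse(g$z == g$y_next,
                   0.5 * A(g$y_now, g$y_next) * A(g$y_next, g$x_now), 0)
  if (!include_z) {
    m <- stats::aggregate(prob ~ y_next + y_now + x_now, g, sum)
    return(m[order(m$y_next, m$y_now, m$x_now), ])
  }
  g
}

#' Synthetic continuous monthly series with trend, seasonality and noise
#'
#' `value(t) = intercept + trend * t + amplitude * s(month(t)) + noise_sd * e`,
#' with `s` a fixed sinusoidal 12-month profile and `e` iid standard normal.
#' Defaults emulate a mid-size state's monthly background-check counts
#' (tens of thousands, a mild upward trend, visible seasonality).
#'
#' @param T months (>= 24).
#' @param trend slope per month.
#' @param amplitude seasonal amplitude.
#' @param noise_sd noise standard deviation.
#' @param intercept level at t = 0.
#' @param seed integer seed.
#' @param start first month.
#' @param id unit label.
#' @return a [monthly_series()].
#' @export
gen_monthly_continuous <- function(T = 228, trend = 50, amplitude = 2000,
                                   noise_sd = 1000, intercept = 20000,
                                   seed = 1, start = "1999-01", id = "sim") {
  if (T < 24L) stop("need T >= 24")
  set.seed(seed)
  months <- month_seq(start, T)
  s <- sin(2 * pi * month_of_year(months) / 12)
  v <- intercept + trend * seq_len(T) + amplitude * s +
    noise_sd * stats::rnorm(T)
  monthly_series(v, start, id = id, kind = "background_checks")
}

#' Synthetic state map with bimodal legal environment and events
#'
#' Generates `n_states` units with centroids on a jittered grid covering a
#' continental-US-like bounding box, populations log-uniform over two orders
#' of magnitude, law restrictiveness drawn from a well-separated two-component
#' normal mixture (restrictive mode 0.70, permissive mode 0.20, sd 0.05,
#' truncated to `[0, 1]`), and a mass-shooting event list with
#' population-proportional state assignment and Poisson monthly counts.
#'
#' @param n_states number of units (>= 4; study analogue 48).
#' @param restrictive_fraction expected fraction of restrictive units
#'   (study analogue 7/48).
#' @param seed integer seed.
#' @param event_rate expected events per month (study analogue 87/228).
#' @param window study window, `c(start, end)` months.
#' @param pop_range population bounds (two orders of magnitude apart).
#' @return list with `states` (data frame: code, name, population, lat, lon,
#'   law_restrictiveness, included, cluster) and `events` (data frame: name,
#'   state, date). Codes are `S01`, `S02`, ... — synthetic units, not real
#'   states.
#' @export
gen_state_map <- function(n_states = 48, restrictive_fraction = 7 / 48,
                          seed = 1, event_rate = 87 / 228,
                          window = c("1999-01", "2017-12"),
                          pop_range = c(5e5, 5e7)) {
  if (n_states < 4L) stop("need at least 4 units")
  set.seed(seed)
  code <- sprintf("S%02d", seq_len(n_states))
  ncol_ <- ceiling(sqrt(n_states))
  row <- (seq_len(n_states) - 1L) %/% ncol_
  col <- (seq_len(n_states) - 1L) %% ncol_
  lat <- 30 + 18 * row / max(1, ncol_ - 1) + stats::runif(n_states, -1, 1)
  lon <- -120 + 45 * col / max(1, ncol_ - 1) + stats::runif(n_states, -1, 1)
  lat <- pmin(pmax(lat, -89), 89)
  population <- round(exp(stats::runif(n_states, log(pop_range[1]),
                                       log(pop_range[2]))))
  n_restr <- round(restrictive_fraction * n_states)
  is_restr <- seq_len(n_states) %in% sample.int(n_states, n_restr)
  mu <- ifelse(is_restr, 0.70, 0.20)
  law <- pmin(pmax(stats::rnorm(n_states, mu, 0.05), 0), 1)
  states <- data.frame(code = code, name = paste("Unit", code),
                       population = population, lat = lat, lon = lon,
                       law_restrictiveness = law, included = TRUE,
                       cluster = NA_character_, stringsAsFactors = FALSE)
  states$cluster <- as.character(kmeans_partition(states$law_restrictiveness))
  Tm <- window_length(window)
  months <- month_seq(window[1], Tm)
  counts <- stats::rpois(Tm, event_rate)
  n_ev <- sum(counts)
  events <- data.frame(name = character(0), state = character(0),
                       date = as.Date(character(0)))
  if (n_ev > 0) {
    st <- sample(code, n_ev, replace = TRUE, prob = population)
    mo <- rep(months, counts)
    day <- sprintf("%02d", sample.int(28, n_ev, replace = TRUE))
    events <- data.frame(name = paste0("synthetic event ", seq_len(n_ev)),
                         state = st,
                         date = as.Date(paste0(mo, "-", day)),
                         stringsAsFactors = FALSE)
  }
  list(states = states, events = events)
}

#' Full synthetic study bundle with planted causal structure
#'
#' Builds a complete analysis-ready world: a synthetic state map, a national
#' mass-shooting series derived from the generated events, iid fair media
#' series (MOfc, MOs), and per-state background-check symbol processes evolved
#' sequentially with planted lag-1 couplings. At each month the next BC symbol
#' of a state copies, in this priority order, MOfc / MS / MOs with the
#' group-specific probabilities in `coupling`, or the current mode of its
#' `n_neighbors` nearest states with probability `coupling$neighbor`, and is
#' otherwise a fair coin.
#'
#' Event records carry the synthetic unit codes (S01, ...); [run_study2()]
#' detects these and matches them verbatim instead of resolving them against
#' the real state table.
#'
#' @param T months.
#' @param n_states units.
#' @param seed master seed.
#' @param coupling list with elements `mofc_bc`, `ms_bc`, `mos_bc` (each a
#'   named vector `c(restrictive = , permissive = )`) and scalars `neighbor`,
#'   `n_neighbors`.
#' @param restrictive_fraction,event_rate passed to [gen_state_map()].
#' @param start first month.
#' @return a [study_bundle()].
#' @export
gen_study_bundle <- function(T = 228, n_states = 48, seed = 1,
                             coupling = list(), restrictive_fraction = 7 / 48,
                             event_rate = 87 / 228, start = "1999-01") {
  cp <- utils::modifyList(
    list(mofc_bc = c(restrictive = 0, permissive = 0),
         ms_bc = c(restrictive = 0, permissive = 0),
         mos_bc = c(restrictive = 0, permissive = 0),
         neighbor = 0, n_neighbors = 3),
    coupling)
  window <- c(start, month_label(month_id(start) + T - 1L))
  map <- gen_state_map(n_states, restrictive_fraction,
                       seed = mix_seed(seed, "map"),
                       event_rate = event_rate, window = window)
  states <- map$states
  ms <- if (nrow(map$events)) {
    # synthetic unit codes are not US states; bin by month directly
    ev <- month_id(format(map$events$date, "%Y-%m"))
    ids <- month_id(start) + seq_len(T) - 1L
    binary_series(as.integer(ids %in% ev), start, id = "MS")
  } else {
    binary_series(rep(c(0L, 1L), length.out = T), start, id = "MS")
  }
  set.seed(mix_seed(seed, "media"))
  mofc <- binary_series(stats::rbinom(T, 1L, 0.5), start, id = "MOfc")
  mos <- binary_series(stats::rbinom(T, 1L, 0.5), start, id = "MOs")

  # neighbor lists for the imitation coupling
  nb <- NULL
  if (cp$neighbor > 0) {
    dk <- distance_matrix(states)
    nb <- lapply(states$code, function(s)
      match(nearest_neighbors(s, states, cp$n_neighbors, dk)$neighbors,
            states$code))
  }
  grp <- states$cluster
  p_mofc <- unname(cp$mofc_bc[grp])
  p_ms <- unname(cp$ms_bc[grp])
  p_mos <- unname(cp$mos_bc[grp])
  p_nb <- rep(cp$neighbor, n_states)

  set.seed(mix_seed(seed, "bc"))
  bc <- matrix(0L, nrow = T, ncol = n_states)
  bc[1, ] <- stats::rbinom(n_states, 1L, 0.5)
  for (t in seq_len(T - 1L)) {
    u <- stats::runif(n_states)
    coin <- stats::rbinom(n_states, 1L, 0.5)
    nxt <- coin
    if (cp$neighbor > 0) {
      mode_t <- vapply(nb, function(idx)
        as.integer(2L * sum(bc[t, idx]) > length(idx)), integer(1))
      pick <- u < p_mofc + p_ms + p_mos + p_nb
      nxt[pick] <- mode_t[pick]
    }
    pick <- u < p_mofc + p_ms + p_mos
    nxt[pick] <- mos[t]
    pick <- u < p_mofc + p_ms
    nxt[pick] <- ms[t]
    pick <- u < p_mofc
    nxt[pick] <- mofc[t]
    bc[t + 1L, ] <- nxt
  }
  bc_list <- stats::setNames(lapply(seq_len(n_states), function(i)
    binary_series(bc[, i], start, id = states$code[i])), states$code)
  study_bundle(states, bc_list, ms, mofc, mos, map$events, window)
}
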