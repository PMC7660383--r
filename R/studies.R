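# The three state-level studies and the conditional-probability maps.
#
# A study bundle holds everything downstream of preprocessing:
#   states    data frame: code, name, population, lat, lon,
#             law_restrictiveness, included, cluster
#   bc        named list: background-check binary series per included state
#   ms        national mass-shooting occurrence binary series
#   mofc      media-output-on-firearm-control binary series (mode-aggregated)
#   mos       media-output-on-shootings binary series (mode-aggregated)
#   events    event data frame (name, state, date)
#   window    c(start, end) months

#' Assemble a study bundle from prepared components
#'
#' @param states state table (see module description above); `cluster` must be
#'   `"restrictive"`, `"permissive"` or `"excluded"`.
#' @param bc named list of per-state background-check [binary_series()].
#' @param ms,mofc,mos national cause [binary_series()].
#' @param events event data frame (`name`, `state`, `date`).
#' @param window `c(start, end)` months.
#' @return a `symte_bundle`.
#' @export
study_bundle <- function(states, bc, ms, mofc, mos, events,
                         window = c("1999-01", "2017-12")) {
  inc <- states$code[states$included]
  missing <- setdiff(inc, names(bc))
  if (length(missing)) {
    stop("missing background-check series for included state(s): ",
         paste(missing, collapse = ", "))
  }
  for (s in inc) check_aligned(bc[[s]], ms, mofc, mos)
  structure(list(states = states, bc = bc, ms = ms, mofc = mofc, mos = mos,
                 events = events, window = window),
            class = "symte_bundle")
}

#' @export
print.symte_bundle <- function(x, ...) {
  cat(sprintf("<symte_bundle> %d states (%d included: %d restrictive, %d permissive), window %s..%s, %d events\n",
              nrow(x$states), sum(x$states$included),
              sum(x$states$cluster == "restrictive"),
              sum(x$states$cluster == "permissive"),
              x$window[1], x$window[2],
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

group_states <- function(bundle, group) {
  st <- bundle$states
  st$code[st$included & st$cluster == group]
}

# Run one table cell: a surrogate test of `cause_of(state)` on the state's
# background checks, conditioned on `conds_of(state)`.
run_cell <- function(bundle, group, cause_of, conds_of, B, seed, ...) {
  codes <- group_states(bundle, group)
  if (!length(codes)) stop("no included states in group '", group, "'")
  st <- bundle$states
  members <- lapply(codes, function(s) {
    list(state = s,
         population = st$population[st$code == s],
         effect = bundle$bc[[s]],
         cause = cause_of(s),
         conds = conds_of(s))
  })
  surrogate_test(group_spec(members), B = B, seed = seed, ...)
}

study_table <- function(rows, study, B, seed, alpha, n = NA_integer_) {
  tab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(group = r$group, cause = r$cause,
               te = r$res$observed, q95 = r$res$q95,
               p = r$res$p_value, p_label = r$res$p_label,
               significant = r$res$p_value < alpha,
               degenerate = paste(r$res$degenerate, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  structure(tab, study = study, B = B, seed = seed, alpha = alpha, n = n,
            class = c("study_table", "data.frame"))
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("== %s (B = %d, seed = %d, alpha = %g%s) ==\n",
              attr(x, "study"), attr(x, "B"), attr(x, "seed"),
              attr(x, "alpha"),
              if (is.na(attr(x, "n"))) "" else paste0(", n = ", attr(x, "n"))))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Study 1: national drivers of state-level background checks
#'
#' For each legal-environment group (restrictive, permissive) and each
#' candidate national cause — mass-shooting occurrence (MS), media output on
#' firearm control (MOfc), media output on shootings (MOs) — computes the
#' group-aggregated conditional transfer entropy onto background checks,
#' conditioning each cause on the other two, with a stratified permutation
#' test. Six cells in total.
#'
#' @param bundle a [study_bundle()].
#' @param B surrogate replicates.
#' @param seed master seed.
#' @param alpha significance level.
#' @param ... passed to [surrogate_test()] (capacity guard options).
#' @return a `study_table` (2 groups x 3 causes).
#' @export
run_study1 <- function(bundle, B = 20000, seed = 1, alpha = 0.050, ...) {
  causes <- list(MS = bundle$ms, MOfc = bundle$mofc, MOs = bundle$mos)
  rows <- list()
  for (g in c("restrictive", "permissive")) {
    for (cn in names(causes)) {
      others <- causes[setdiff(names(causes), cn)]
      res <- run_cell(bundle, g,
                      cause_of = function(s) causes[[cn]],
                      conds_of = function(s) unname(others),
                      B = B, seed = mix_seed(seed, paste0("s1_", g, "_", cn)),
                      ...)
      rows[[length(rows) + 1L]] <- list(group = g, cause = cn, res = res)
    }
  }
  study_table(rows, "study1", B, seed, alpha)
}

#' Study 2: location of the mass shooting
#'
#' For each state the national event list is split into in-state occurrences
#' (MSst) and occurrences anywhere else in the Nation including excluded units
#' (MSe); each is tested as a cause of the state's background checks,
#' conditioned on the other. States with no local shootings have a constant
#' MSst series: they contribute zero transfer entropy and are flagged in the
#' `degenerate` column.
#'
#' @inheritParams run_study1
#' @return a `study_table` (2 groups x 2 causes).
#' @export
run_study2 <- function(bundle, B = 20000, seed = 1, alpha = 0.050, ...) {
  # synthetic bundles carry unit codes (S01, ...) that are not US states
  resolve <- !all(bundle$events$state %in% bundle$states$code)
  msst <- list(); mse <- list()
  for (s in bundle$states$code[bundle$states$included]) {
    msst[[s]] <- events_to_binary(bundle$events, bundle$window, "in_state", s,
                                  resolve = resolve)
    mse[[s]] <- events_to_binary(bundle$events, bundle$window, "elsewhere", s,
                                 resolve = resolve)
  }
  rows <- list()
  for (g in c("restrictive", "permissive")) {
    for (cn in c("MSst", "MSe")) {
      res <- run_cell(bundle, g,
                      cause_of = function(s)
                        if (cn == "MSst") msst[[s]] else mse[[s]],
                      conds_of = function(s)
                        if (cn == "MSst") list(mse[[s]]) else list(msst[[s]]),
                      B = B, seed = mix_seed(seed, paste0("s2_", g, "_", cn)),
                      ...)
      rows[[length(rows) + 1L]] <- list(group = g, cause = cn, res = res)
    }
  }
  study_table(rows, "study2", B, seed, alpha)
}

#' Study 3: influence of geographically neighboring states
#'
#' For each number of neighbors `n`, each state's neighbor-interaction series
#' BC-bar (per-month mode of the background-check symbols of its `n` nearest
#' included states) is tested as a cause of its background checks, controlling
#' for the two media drivers (MOfc, MOs); the media causes are in turn each
#' conditioned on the remaining two of the trio.
#'
#' @inheritParams run_study1
#' @param n_list numbers of neighbors (study values 1, 3, 5, 7, 9).
#' @param dist_km optional precomputed distance matrix.
#' @return list of `study_table`s, one per `n` (each 2 groups x 3 causes).
#' @export
run_study3 <- function(bundle, n_list = c(1, 3, 5, 7, 9), B = 20000,
                       seed = 1, alpha = 0.050, dist_km = NULL, ...) {
  if (is.null(dist_km)) dist_km <- distance_matrix(bundle$states)
  inc <- bundle$states$code[bundle$states$included]
  out <- list()
  for (n in n_list) {
    bcbar <- stats::setNames(lapply(inc, function(s)
      neighbor_mode_series(s, n, bundle$bc, bundle$states, dist_km)), inc)
    causes <- c("BCbar", "MOfc", "MOs")
    rows <- list()
    for (g in c("restrictive", "permissive")) {
      for (cn in causes) {
        cause_of <- switch(cn,
                           BCbar = function(s) bcbar[[s]],
                           MOfc = function(s) bundle$mofc,
                           MOs = function(s) bundle$mos)
        conds_of <- switch(cn,
                           BCbar = function(s) list(bundle$mofc, bundle$mos),
                           MOfc = function(s) list(bcbar[[s]], bundle$mos),
                           MOs = function(s) list(bcbar[[s]], bundle$mofc))
        res <- run_cell(bundle, g, cause_of, conds_of, B = B,
                        seed = mix_seed(seed, paste0("s3_", n, "_", g, "_", cn)),
                        ...)
        rows[[length(rows) + 1L]] <- list(group = g, cause = cn, res = res)
      }
    }
    out[[paste0("n", n)]] <- study_table(rows, "study3", B, seed, alpha, n = n)
  }
  out
}

#' Conditional transition probability of background checks
#'
#' Plug-in estimate of
#' `P(BC(t+1) = up | BC(t) = down, cause(t) = cause_value)`, the quantity
#' behind the per-state probability maps. Returns `NA` when the conditioning
#' event never occurs.
#'
#' @param bc background-check [binary_series()].
#' @param cause aligned cause [binary_series()].
#' @param cause_value conditioning symbol, 0 (down) or 1 (up).
#' @return probability in `[0, 1]`, or `NA`.
#' @export
conditional_prob_map <- function(bc, cause, cause_value = 1L) {
  check_aligned(bc, cause)
  T <- length(bc)
  y <- unclass(bc); x <- unclass(cause)
  sel <- y[-T] == 0L & x[-T] == as.integer(cause_value)
  if (!any(sel)) return(NA_real_)
  mean(y[-1L][sel] == 1L)
}

#' Per-state conditional-probability table
#'
#' Tabulates [conditional_prob_map()] for every included state and each
#' national cause and symbol value, in the layout consumed by choropleth
#' plotting.
#'
#' @param bundle a [study_bundle()].
#' @return data frame with columns `state`, `cause`, `cause_value`, `prob`.
#' @export
prob_map_table <- function(bundle) {
  causes <- list(MS = bundle$ms, MOfc = bundle$mofc, MOs = bundle$mos)
  inc <- bundle$states$code[bundle$states$included]
  grid <- expand.grid(state = inc, cause = names(causes),
                      cause_value = c(0L, 1L), stringsAsFactors = FALSE)
  grid$prob <- mapply(function(s, cn, v)
    conditional_prob_map(bundle$bc[[s]], causes[[cn]], v),
    grid$state, grid$cause, grid$cause_value)
  grid[order(grid$state, grid$cause, grid$cause_value), , drop = FALSE]
}
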