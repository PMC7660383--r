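# Readers and writers for the plain-CSV interchange formats, the JSON study
# configuration, result serialization with provenance, and bundle assembly
# from raw inputs.

#' Read a mass-shooting event list
#'
#' Expects columns `name`, `state`, `date` (ISO dates). Rows with malformed
#' dates or unresolvable states are reported with their line numbers.
#'
#' @param path CSV file.
#' @param resolve validate states against the 50 states + DC.
#' @return data frame with `name`, `state` (2-letter code), `date` (`Date`).
#' @export
read_events <- function(path, resolve = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "state", "date")
  if (!all(need %in% names(df))) {
    stop("events file needs columns ", paste(need, collapse = ", "))
  }
  if (!nrow(df)) {
    return(data.frame(name = character(0), state = character(0),
                      date = as.Date(character(0))))
  }
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("malformed date(s) at line(s): ",
         paste(which(is.na(dates)) + 1L, collapse = ", "))
  }
  states <- as.character(df$state)
  if (resolve) {
    known <- toupper(c(datasets::state.abb, "DC", datasets::state.name,
                       "District of Columbia"))
    bad <- which(!toupper(trimws(states)) %in% known)
    if (length(bad)) {
      stop("unresolvable state at line(s): ", paste(bad + 1L, collapse = ", "))
    }
    states <- resolve_state(states)
  }
  data.frame(name = df$name, state = states, date = dates,
             stringsAsFactors = FALSE)
}

#' The packaged mass-shooting event table (1999-2017)
#'
#' Loads the 87-event list (name, state, date) shipped with the package.
#'
#' @return event data frame as from [read_events()].
#' @export
packaged_events <- function() {
  read_events(system.file("extdata", "mass_shootings_1999_2017.csv",
                          package = "symte", mustWork = TRUE))
}

#' Read monthly series in long CSV form
#'
#' Format: columns `month` (`YYYY-MM`), `unit_id`, `value`. Each unit's months
#' must be consecutive; a gap is reported with the first missing month.
#'
#' @param path CSV file.
#' @param kind series kind label (see [monthly_series()]).
#' @return named list of [monthly_series()], one per unit.
#' @export
read_series <- function(path, kind = "raw") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("month", "unit_id", "value")
  if (!all(need %in% names(df))) {
    stop("series file needs columns ", paste(need, collapse = ", "))
  }
  out <- list()
  for (u in unique(df$unit_id)) {
    d <- df[df$unit_id == u, , drop = FALSE]
    ids <- month_id(d$month)
    o <- order(ids)
    ids <- ids[o]
    gap <- which(diff(ids) != 1L)
    if (length(gap)) {
      stop("unit '", u, "': gap in monthly calendar, missing month ",
           month_label(ids[gap[1]] + 1L))
    }
    out[[u]] <- monthly_series(d$value[o], start = month_label(ids[1]),
                               id = u, kind = kind)
  }
  out
}

#' Read the state metadata table
#'
#' Format: `code,name,population,lat,lon,law_restrictiveness,included`.
#'
#' @param path CSV file.
#' @return data frame with validated columns and an empty `cluster` column.
#' @export
read_states <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "name", "population", "lat", "lon",
            "law_restrictiveness", "included")
  if (!all(need %in% names(df))) {
    stop("states file needs columns ", paste(need, collapse = ", "))
  }
  df$included <- as.logical(df$included)
  bad <- which(df$included & df$population <= 0)
  if (length(bad)) {
    stop("non-positive population for included state(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  }
  if (any(df$law_restrictiveness < 0 | df$law_restrictiveness > 1)) {
    stop("law_restrictiveness must be in [0, 1]")
  }
  if (!"cluster" %in% names(df)) df$cluster <- NA_character_
  df
}

#' Write / read a binary series as CSV
#'
#' On-disk encoding: columns `month` (`YYYY-MM`) and `symbol` (0 = down,
#' 1 = up).
#'
#' @param x a [binary_series()].
#' @param path CSV file.
#' @param id unit label for the series read back.
#' @return `read_binary_csv` returns a [binary_series()].
#' @export
write_binary_csv <- function(x, path) {
  utils::write.csv(data.frame(month = series_months(x),
                              symbol = as.integer(x)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_binary_csv
#' @export
read_binary_csv <- function(path, id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- month_id(df$month)
  o <- order(ids)
  if (any(diff(ids[o]) != 1L)) stop("binary series has non-monthly gaps")
  binary_series(df$symbol[o], start = month_label(ids[o][1]), id = id)
}

#' Study configuration
#'
#' Merges user settings (a JSON file and/or overrides) over the study
#' defaults: window 1999-01..2017-12, exclusions Connecticut and Hawaii,
#' B = 20000 surrogates, alpha = 0.050, neighbor counts 1,3,5,7,9, master
#' seed 1, capacity floor 5 samples/cell.
#'
#' @param path optional JSON file.
#' @param ... named overrides applied after the file.
#' @return a `symte_config` list.
#' @export
read_config <- function(path = NULL, ...) {
  cfg <- list(window = c("1999-01", "2017-12"),
              exclude = c("CT", "HI"),
              B = 20000, alpha = 0.050, seed = 1,
              n_list = c(1, 3, 5, 7, 9),
              min_samples_per_cell = 5,
              paths = list())
  if (!is.null(path)) {
    cfg <- utils::modifyList(cfg, jsonlite::read_json(path, simplifyVector = TRUE))
  }
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$B < 1) stop("B must be >= 1")
  if (window_length(cfg$window) < 24) stop("window must span >= 24 months")
  structure(cfg, class = c("symte_config", "list"))
}

#' Deterministic configuration hash
#'
#' Polynomial rolling hash of the canonical JSON serialization; changes
#' whenever any configuration value changes. Used to stamp result provenance.
#'
#' @param cfg any jsonlite-serializable object.
#' @return hexadecimal string.
#' @export
config_hash <- function(cfg) {
  s <- as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Prepare a study bundle from raw inputs
#'
#' The full preprocessing path: excluded states are dropped, included states
#' are clustered on law restrictiveness, raw background-check counts are
#' seasonally adjusted + detrended and sign-symbolized, per-outlet media
#' counts are median-symbolized and mode-aggregated, and the national
#' mass-shooting series is built from the event list.
#'
#' @param states state table ([read_states()]).
#' @param events event list ([read_events()]).
#' @param bc_series named list of raw background-check [monthly_series()] per
#'   state code.
#' @param media_fc_series,media_s_series lists of per-outlet [monthly_series()]
#'   (firearm-control and shootings coverage).
#' @param config a [read_config()] object.
#' @return a [study_bundle()].
#' @export
prepare_bundle <- function(states, events, bc_series,
                           media_fc_series, media_s_series,
                           config = read_config()) {
  window <- config$window
  states$included <- states$included & !(states$code %in% config$exclude)
  states$cluster <- "excluded"
  inc <- states$included
  states$cluster[inc] <-
    as.character(kmeans_partition(states$law_restrictiveness[inc]))
  bc <- list()
  for (s in states$code[inc]) {
    if (is.null(bc_series[[s]])) {
      stop("missing background-check series for included state: ", s)
    }
    bc[[s]] <- symbolize_sign(seasonal_adjust_detrend(
      clip_months(bc_series[[s]], window)))
  }
  symbolize_outlets <- function(lst, id) {
    aggregate_mode(lapply(lst, function(m)
      symbolize_median(clip_months(m, window))), id = id)
  }
  mofc <- symbolize_outlets(media_fc_series, "MOfc")
  mos <- symbolize_outlets(media_s_series, "MOs")
  ms <- events_to_binary(events, window, "national")
  study_bundle(states, bc, ms, mofc, mos, events, window)
}

#' Write study tables with provenance
#'
#' Each table becomes `<study>[_n<k>].csv` (cells ordered as in the study
#' tables: restrictive before permissive, causes in column order) next to a
#' JSON sidecar with seed, B, alpha and the configuration hash.
#'
#' @param tables a `study_table` or list of them.
#' @param dir output directory (created if needed).
#' @param config configuration recorded in the sidecar.
#' @return invisible character vector of files written.
#' @export
write_results <- function(tables, dir, config = read_config()) {
  if (inherits(tables, "study_table")) tables <- list(tables)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (tab in tables) {
    stem <- attr(tab, "study")
    if (!is.na(attr(tab, "n"))) stem <- paste0(stem, "_n", attr(tab, "n"))
    f <- file.path(dir, paste0(stem, ".csv"))
    utils::write.csv(as.data.frame(tab), f, row.names = FALSE)
    sidecar <- list(study = attr(tab, "study"), n = attr(tab, "n"),
                    B = attr(tab, "B"), seed = attr(tab, "seed"),
                    alpha = attr(tab, "alpha"),
                    exclude = config$exclude,
                    config_hash = config_hash(unclass(config)))
    jf <- file.path(dir, paste0(stem, ".json"))
    jsonlite::write_json(sidecar, jf, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    files <- c(files, f, jf)
  }
  invisible(files)
}

#' Write / read a symbolized study bundle as a directory of CSV files
#'
#' Layout: `states.csv`, `events.csv`, `bc.csv` (long: month, unit_id,
#' symbol), `national.csv` (month, MS, MOfc, MOs), `window.json`.
#'
#' @param bundle a [study_bundle()].
#' @param dir directory.
#' @return `read_bundle` returns a [study_bundle()].
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$states, file.path(dir, "states.csv"),
                   row.names = FALSE)
  ev <- bundle$events
  ev$date <- format(as.Date(ev$date), "%Y-%m-%d")
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  bc_long <- do.call(rbind, lapply(names(bundle$bc), function(s)
    data.frame(month = series_months(bundle$bc[[s]]), unit_id = s,
               symbol = as.integer(bundle$bc[[s]]))))
  utils::write.csv(bc_long, file.path(dir, "bc.csv"), row.names = FALSE)
  utils::write.csv(data.frame(month = series_months(bundle$ms),
                              MS = as.integer(bundle$ms),
                              MOfc = as.integer(bundle$mofc),
                              MOs = as.integer(bundle$mos)),
                   file.path(dir, "national.csv"), row.names = FALSE)
  jsonlite::write_json(list(window = bundle$window),
                       file.path(dir, "window.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  states <- read_states(file.path(dir, "states.csv"))
  resolve <- all(toupper(states$code) %in% c(datasets::state.abb, "DC"))
  events <- read_events(file.path(dir, "events.csv"), resolve = resolve)
  window <- unlist(jsonlite::read_json(file.path(dir, "window.json"),
                                       simplifyVector = TRUE)$window)
  bc_long <- utils::read.csv(file.path(dir, "bc.csv"),
                             stringsAsFactors = FALSE)
  bc <- list()
  for (u in unique(bc_long$unit_id)) {
    d <- bc_long[bc_long$unit_id == u, ]
    o <- order(month_id(d$month))
    bc[[u]] <- binary_series(d$symbol[o], start = d$month[o][1], id = u)
  }
  nat <- utils::read.csv(file.path(dir, "national.csv"),
                         stringsAsFactors = FALSE)
  o <- order(month_id(nat$month))
  start <- nat$month[o][1]
  study_bundle(states, bc,
               ms = binary_series(nat$MS[o], start, id = "MS"),
               mofc = binary_series(nat$MOfc[o], start, id = "MOfc"),
               mos = binary_series(nat$MOs[o], start, id = "MOs"),
               events = events, window = window)
}
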