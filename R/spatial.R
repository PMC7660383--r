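# Geodesic neighbor machinery: great-circle distances between state centroids,
# nearest-neighbor sets, and the neighbor-interaction (mode) series.

EARTH_RADIUS_KM <- 6371

#' Great-circle distance between centroids
#'
#' Haversine formula on a sphere of radius 6371 km. Vectorized over all
#' arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees; latitudes in
#'   `[-90, 90]`, longitudes in `[-180, 180]`.
#' @param radius sphere radius in kilometers.
#' @return distance(s) in kilometers.
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2,
                              radius = EARTH_RADIUS_KM) {
  lats <- c(lat1, lat2); lons <- c(lon1, lon2)
  if (anyNA(lats) || anyNA(lons) ||
      any(abs(lats) > 90) || any(abs(lons) > 180)) {
    stop("coordinates out of range: need |lat| <= 90, |lon| <= 180")
  }
  to_rad <- pi / 180
  dphi <- (lat2 - lat1) * to_rad / 2
  dlam <- (lon2 - lon1) * to_rad / 2
  a <- sin(dphi)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlam)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

#' Full symmetric distance matrix between state centroids
#'
#' @param states data frame with columns `code`, `lat`, `lon`.
#' @return symmetric matrix (km) with zero diagonal, dimnames = codes.
#' @export
distance_matrix <- function(states) {
  n <- nrow(states)
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    geodesic_distance(states$lat[i], states$lon[i],
                      states$lat[j], states$lon[j])
  })
  dimnames(d) <- list(states$code, states$code)
  d
}

#' The n geodesically nearest included states
#'
#' Neighbors are drawn from the included states only (excluded units have no
#' usable background-check series) and irrespective of their legal-environment
#' cluster. Distance ties break lexicographically by state code.
#'
#' @param focal 2-letter code of the focal state.
#' @param states data frame with columns `code`, `lat`, `lon` and logical
#'   `included`.
#' @param n number of neighbors; must be less than the number of included
#'   states other than the focal.
#' @param dist_km optional precomputed distance matrix (dimnames = codes),
#'   e.g. read from file, overriding on-the-fly haversine computation.
#' @return a `neighbor_set`: list with `focal`, `neighbors` (codes, nearest
#'   first) and `n`.
#' @export
nearest_neighbors <- function(focal, states, n, dist_km = NULL) {
  pool <- states[states$included & states$code != focal, , drop = FALSE]
  if (n >= nrow(pool) + 1L || n > nrow(pool)) {
    stop("n = ", n, " neighbors requested but only ", nrow(pool),
         " included states available")
  }
  if (is.null(dist_km)) {
    f <- states[states$code == focal, , drop = FALSE]
    if (nrow(f) != 1L) stop("focal state '", focal, "' not found")
    d <- geodesic_distance(f$lat, f$lon, pool$lat, pool$lon)
  } else {
    d <- dist_km[focal, pool$code]
  }
  o <- order(d, pool$code)
  structure(list(focal = focal, neighbors = pool$code[o][seq_len(n)], n = n),
            class = "neighbor_set")
}

#' @export
print.neighbor_set <- function(x, ...) {
  cat(sprintf("<neighbor_set> %s: %s\n", x$focal,
              paste(x$neighbors, collapse = " > ")))
  invisible(x)
}

#' Neighbor-interaction series: per-month mode of the nearest states
#'
#' Builds the aggregate background-check symbol of the `n` states nearest to
#' the focal state (the BC-bar cause series of the spatial study).
#'
#' @param focal 2-letter code of the focal state.
#' @param n number of neighbors (odd values avoid mode ties).
#' @param bc_binary named list mapping state code to its background-check
#'   [binary_series()].
#' @param states data frame as in [nearest_neighbors()].
#' @param dist_km optional precomputed distance matrix.
#' @return a [binary_series()] labelled `BCbar_<focal>`.
#' @export
neighbor_mode_series <- function(focal, n, bc_binary, states, dist_km = NULL) {
  ns <- nearest_neighbors(focal, states, n, dist_km)
  missing <- setdiff(ns$neighbors, names(bc_binary))
  if (length(missing)) {
    stop("missing background-check series for neighbor state(s): ",
         paste(missing, collapse = ", "))
  }
  aggregate_mode(bc_binary[ns$neighbors], id = paste0("BCbar_", focal))
}
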