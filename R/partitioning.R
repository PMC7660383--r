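# Legal-environment partitioning: law-restrictiveness fractions and an exact
# one-dimensional two-means split into restrictive vs permissive states.

#' Law-restrictiveness fraction from yearly law counts
#'
#' The mean over years of the fraction of the catalogued laws in effect
#' (133 firearm safety laws in the source catalogue).
#'
#' @param laws_in_effect_by_year numeric vector of per-year counts of laws in
#'   effect.
#' @param total_laws size of the law catalogue.
#' @return fraction in `[0, 1]`.
#' @export
law_restrictiveness_fraction <- function(laws_in_effect_by_year,
                                         total_laws = 133) {
  if (total_laws <= 0) stop("total_laws must be positive")
  cnt <- as.numeric(laws_in_effect_by_year)
  if (!length(cnt)) stop("need at least one yearly count")
  if (anyNA(cnt) || any(cnt < 0)) stop("negative or missing yearly counts")
  if (any(cnt > total_laws)) stop("yearly count exceeds total_laws")
  mean(cnt / total_laws)
}

#' Exact two-group k-means partition of scalar values
#'
#' In one dimension with k = 2 the optimal k-means (Euclidean) partition is an
#' interval split, so the global optimum is found deterministically by scanning
#' all `n - 1` split points of the sorted values and minimizing the
#' within-cluster sum of squares — no random initialization. The cluster with
#' the larger mean is labelled `"restrictive"`, the other `"permissive"`.
#'
#' @param values numeric vector with at least two distinct values.
#' @return character vector aligned with `values`, each element
#'   `"restrictive"` or `"permissive"`; the optimal threshold is attached as
#'   attribute `threshold` (midpoint of the split gap).
#' @export
kmeans_partition <- function(values) {
  x <- as.numeric(values)
  if (anyNA(x)) stop("values must not be NA")
  if (length(unique(x)) < 2L) stop("need at least 2 distinct values to split")
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  m <- seq_len(n - 1L)
  # within-cluster SS of split {1..m | m+1..n} via sum x^2 - (sum x)^2 / n
  wss <- (cs2[m] - cs[m]^2 / m) +
         ((cs2[n] - cs2[m]) - (cs[n] - cs[m])^2 / (n - m))
  # only consider splits between distinct values (ties must stay together)
  valid <- xs[m] < xs[m + 1L]
  if (!any(valid)) stop("need at least 2 distinct values to split")
  best <- m[valid][which.min(wss[valid])]
  thr <- (xs[best] + xs[best + 1L]) / 2
  labels <- ifelse(x > thr, "restrictive", "permissive")
  attr(labels, "threshold") <- thr
  labels
}
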