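# Plug-in estimation of entropy, transfer entropy and conditional (partial)
# transfer entropy on binary symbolic series, plus an exact-pmf oracle.
#
# All estimators are lag-1: the transition sample at time t pairs
# (Y(t+1), Y(t), X(t), Z1(t), ..., Zq(t)), giving T - 1 samples from a series
# of length T. Conditional entropies are differences of joint plug-in
# entropies, H(A | B) = H(A, B) - H(B); no bias correction is applied (the
# permutation null absorbs estimator bias).

#' Plug-in entropy of a symbol histogram
#'
#' Computes \eqn{-\sum_k p_k \log_2 p_k} with \eqn{p_k} the empirical
#' frequencies; \eqn{0 \log 0} is treated as 0. The result is in bits and lies
#' in \eqn{[0, \log_2 K]} for K histogram cells.
#'
#' @param counts nonnegative numeric vector of symbol counts (named or not).
#' @return entropy in bits.
#' @export
plugin_entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L) stop("empty histogram: no observations")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative")
  n <- sum(counts)
  if (n <= 0) stop("empty histogram: no observations")
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# entropy of an integer code vector (codes in 0..(nbins-1))
ent_codes <- function(codes, nbins) {
  cnt <- tabulate(codes + 1L, nbins)
  n <- length(codes)
  p <- cnt[cnt > 0L] / n
  -sum(p * log2(p))
}

# Encode conditioning series list as one integer code vector in 0..(2^q - 1)
# for transition times t = 1..T-1 (i.e. symbols at time t).
encode_conds <- function(conds, n) {
  if (length(conds) == 0L) return(NULL)
  z <- integer(n)
  for (s in conds) z <- z * 2L + unclass(s)[seq_len(n)]
  z
}

# Workhorse: conditional transfer entropy from transition-sample code vectors.
# y1, y0, x0 in {0,1}; z integer codes in 0..(nz-1) or NULL.
cte_codes <- function(y1, y0, x0, z = NULL, nz = 1L) {
  if (is.null(z)) {
    z <- 0L
    nz <- 1L
  }
  b_code <- y0 * nz + z                      # (Y(t), Z(t))
  a_code <- y1 * (2L * nz) + b_code          # (Y(t+1), Y(t), Z(t))
  d_code <- (y0 * 2L + x0) * nz + z          # (Y(t), X(t), Z(t))
  c_code <- y1 * (4L * nz) + d_code          # (Y(t+1), Y(t), X(t), Z(t))
  v <- ent_codes(a_code, 4L * nz) - ent_codes(b_code, 2L * nz) -
       ent_codes(c_code, 8L * nz) + ent_codes(d_code, 4L * nz)
  max(v, 0)   # clamp float noise; plug-in CMI is nonnegative
}

new_te_estimate <- function(value, cause_id, effect_id, conditioning_ids) {
  structure(list(value = value,
                 cause_id = cause_id %||% NA_character_,
                 effect_id = effect_id %||% NA_character_,
                 conditioning_ids = conditioning_ids),
            class = "te_estimate")
}

#' @export
print.te_estimate <- function(x, ...) {
  cond <- if (length(x$conditioning_ids)) {
    paste0(" | (", paste(x$conditioning_ids, collapse = ", "), ")")
  } else ""
  cat(sprintf("TE %s -> %s%s = %.4f bits\n",
              x$cause_id, x$effect_id, cond, x$value))
  invisible(x)
}

#' Joint transition histogram of aligned binary series
#'
#' One tuple `(Y(t+1), Y(t), X(t), Z1(t), ..., Zq(t))` is tallied per adjacent
#' month pair, so the total count is `T - 1`.
#'
#' @param effect,cause aligned [binary_series()] objects (the Y and X process).
#' @param conds list of aligned conditioning [binary_series()] (the Z
#'   processes), possibly empty.
#' @return a `joint_histogram`: list with `counts` (named integer vector keyed
#'   by comma-separated tuples in the order above), `arity` (`q + 3`) and `n`
#'   (`T - 1`).
#' @export
build_joint_histogram <- function(effect, cause, conds = list()) {
  check_aligned(effect, cause, conds = NULL)
  for (s in conds) check_aligned(effect, s)
  T <- length(effect)
  n <- T - 1L
  cols <- c(list(unclass(effect)[-1L], unclass(effect)[-T], unclass(cause)[-T]),
            lapply(conds, function(s) unclass(s)[-T]))
  key <- do.call(paste, c(cols, sep = ","))
  counts <- table(key)
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 arity = length(cols),
                 n = n),
            class = "joint_histogram")
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("<joint_histogram> arity %d, %d samples, %d occupied cells\n",
              x$arity, x$n, length(x$counts)))
  invisible(x)
}

#' Export a joint histogram as JSON (debugging aid)
#'
#' @param hist a `joint_histogram`.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
histogram_to_json <- function(hist, path = NULL) {
  js <- jsonlite::toJSON(list(arity = hist$arity, n = hist$n,
                              counts = as.list(hist$counts)),
                         auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# Shared capacity guard. q conditioning processes + (Y(t+1), Y(t), X(t)) give
# 2^(q+3) cells; with fewer than min_per_cell transition samples per cell the
# plug-in joint is badly undersampled.
check_capacity <- function(n, q, min_per_cell = 5, strict = FALSE) {
  cells <- 2^(q + 3)
  if (n < min_per_cell * cells) {
    msg <- sprintf(paste0("capacity: %d transition samples for %d joint cells ",
                          "(< %g per cell); reduce conditioning processes"),
                   n, cells, min_per_cell)
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  invisible(TRUE)
}

#' Transfer entropy between two binary series
#'
#' Lag-1 transfer entropy
#' \eqn{TE_{X \to Y} = H(Y(t+1) | Y(t)) - H(Y(t+1) | Y(t), X(t))}, estimated by
#' plug-in frequencies over the `T - 1` transition samples.
#'
#' @param cause,effect aligned [binary_series()] (X and Y).
#' @return a `te_estimate` with nonnegative `value` in bits.
#' @export
transfer_entropy <- function(cause, effect) {
  conditional_transfer_entropy(cause, effect, conds = list())
}

#' Conditional (partial) transfer entropy
#'
#' \eqn{TE_{X \to Y | Z_1..Z_q} = H(Y(t+1) | Y(t), Z(t)) -
#' H(Y(t+1) | Y(t), X(t), Z(t))}; with an empty conditioning set this is
#' identical to [transfer_entropy()]. Conditional entropies are computed as
#' differences of joint plug-in entropies.
#'
#' @param cause,effect aligned [binary_series()] (X and Y).
#' @param conds list of aligned conditioning [binary_series()].
#' @param min_samples_per_cell capacity floor: a warning (or an error when
#'   `strict = TRUE`) is raised unless `T - 1 >= min_samples_per_cell *
#'   2^(q+3)`.
#' @param strict escalate the capacity warning to an error.
#' @return a `te_estimate` with nonnegative `value` in bits.
#' @export
conditional_transfer_entropy <- function(cause, effect, conds = list(),
                                         min_samples_per_cell = 5,
                                         strict = FALSE) {
  check_aligned(effect, cause)
  for (s in conds) check_aligned(effect, s)
  T <- length(effect)
  n <- T - 1L
  q <- length(conds)
  check_capacity(n, q, min_samples_per_cell, strict)
  y <- unclass(effect)
  x <- unclass(cause)
  z <- encode_conds(conds, n)
  v <- cte_codes(y[-1L], y[-T], x[-T], z, nz = if (q) 2L^q else 1L)
  new_te_estimate(v,
                  cause_id = attr(cause, "id"),
                  effect_id = attr(effect, "id"),
                  conditioning_ids = vapply(conds, function(s)
                    attr(s, "id") %||% NA_character_, character(1)))
}

#' Exact conditional transfer entropy from a supplied joint pmf
#'
#' The test oracle: evaluates the conditional-transfer-entropy functional on an
#' exactly known joint distribution of `(Y(t+1), Y(t), X(t), Z1(t), ...,
#' Zq(t))`, with no estimation.
#'
#' @param pmf data frame whose last column `prob` holds probabilities and whose
#'   preceding columns are the tuple variables in the order `y_next`, `y_now`,
#'   `x_now`, then conditioning variables; or a `joint_histogram`, whose counts
#'   are normalized.
#' @param tol tolerance for the normalization check.
#' @return exact value in bits.
#' @export
te_from_pmf <- function(pmf, tol = 1e-8) {
  if (inherits(pmf, "joint_histogram")) pmf <- histogram_pmf(pmf)
  stopifnot(is.data.frame(pmf), "prob" %in% names(pmf))
  p <- pmf$prob
  if (any(p < -tol)) stop("pmf has negative probabilities")
  if (abs(sum(p) - 1) > tol) stop("pmf is not normalized (sums to ", sum(p), ")")
  vars <- setdiff(names(pmf), "prob")
  if (length(vars) < 3L) stop("pmf needs at least (y_next, y_now, x_now)")
  y1 <- pmf[[vars[1]]]; y0 <- pmf[[vars[2]]]; x0 <- pmf[[vars[3]]]
  zc <- if (length(vars) > 3L) {
    do.call(paste, c(pmf[vars[-(1:3)]], sep = ","))
  } else rep("", length(p))
  ent_of <- function(key) {
    q <- tapply(p, key, sum)
    q <- q[q > 0]
    -sum(q * log2(q))
  }
  v <- ent_of(paste(y1, y0, zc)) - ent_of(paste(y0, zc)) -
       ent_of(paste(y1, y0, x0, zc)) + ent_of(paste(y0, x0, zc))
  max(v, 0)
}

#' Convert a joint histogram to a pmf data frame
#'
#' Normalizes the transition counts so the result can be fed to
#' [te_from_pmf()]; by construction `te_from_pmf(histogram_pmf(h))` equals the
#' plug-in estimate on the generating series.
#'
#' @param hist a `joint_histogram`.
#' @return data frame with tuple columns and a `prob` column.
#' @export
histogram_pmf <- function(hist) {
  key <- strsplit(names(hist$counts), ",", fixed = TRUE)
  m <- do.call(rbind, lapply(key, as.integer))
  out <- as.data.frame(m)
  names(out) <- c("y_next", "y_now", "x_now",
                  if (ncol(m) > 3) paste0("z", seq_len(ncol(m) - 3)))
  out$prob <- as.numeric(hist$counts) / sum(hist$counts)
  out
}
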