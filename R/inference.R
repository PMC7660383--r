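# Significance machinery: structure-preserving stratified permutations of the
# cause series, population-weighted aggregation of per-state conditional
# transfer entropy, and the surrogate (permutation) test.

# Deterministic 31-bit stream seed from (master seed, state key, salt).
mix_seed <- function(master, key, salt = 0L) {
  h <- (abs(as.double(master)) + as.double(salt) * 7919) %% 2147483647
  for (b in utf8ToInt(as.character(key))) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Stratified permutation of a cause series
#'
#' Shuffles the cause symbols only among time instants sharing the same
#' present-time tuple of the effect and conditioning processes
#' `(Y(t), Z1(t), ..., Zq(t))`, so the joint histogram of
#' `(X(t), Y(t), Z(t))` is preserved exactly and only the association between
#' `X(t)` and `Y(t+1)` given the stratum is destroyed. Strata cover the
#' transition times `t = 1..T-1`; the final cause symbol (which enters no
#' transition sample) is left in place.
#'
#' @param cause a [binary_series()] of length T.
#' @param strata vector of stratum labels of length `T - 1`.
#' @return a [binary_series()] on the same calendar.
#' @export
stratified_permute <- function(cause, strata) {
  x <- unclass(cause)
  T <- length(x)
  if (length(strata) != T - 1L) {
    stop("strata length ", length(strata), " does not match T - 1 = ", T - 1L)
  }
  idx <- split(seq_len(T - 1L), strata)
  x[seq_len(T - 1L)] <- permute_within(x[seq_len(T - 1L)], idx)
  binary_series(x, start = series_months(cause)[1], id = attr(cause, "id"))
}

# shuffle values of x within each index block (uses the current RNG state)
permute_within <- function(x, idx_list) {
  for (idx in idx_list) {
    if (length(idx) > 1L) x[idx] <- x[idx[sample.int(length(idx))]]
  }
  x
}

# Stratum labels for the transition times of an effect/conditioning set.
strata_of <- function(effect, conds = list()) {
  T <- length(effect)
  n <- T - 1L
  z <- encode_conds(conds, n)
  y0 <- unclass(effect)[-T]
  if (is.null(z)) y0 else y0 * (2L ^ length(conds)) + z
}

#' Population-weighted aggregation of per-state transfer entropy
#'
#' The group statistic is
#' \deqn{(\sum_s pop_s \sqrt{TE_s})^2 / \sum_s pop_s^2,}
#' the square of the population-weighted sum of root transfer entropies
#' divided by the sum of squared populations (variance controls entropy to
#' first approximation, so root-TE adds like a standard deviation). The value
#' is invariant to rescaling all populations by a common factor and collapses
#' to the single state's TE for a one-state group.
#'
#' @param per_state_te named numeric vector of nonnegative per-state TE (bits).
#' @param populations named numeric vector of positive populations, same
#'   names.
#' @return aggregated value in bits.
#' @export
aggregate_group_te <- function(per_state_te, populations) {
  if (!length(per_state_te)) stop("empty group")
  if (!is.null(names(per_state_te)) && !is.null(names(populations))) {
    if (!setequal(names(per_state_te), names(populations))) {
      stop("state keys of TE values and populations differ")
    }
    populations <- populations[names(per_state_te)]
  } else if (length(per_state_te) != length(populations)) {
    stop("TE values and populations differ in length")
  }
  if (any(per_state_te < 0)) stop("negative transfer entropy input")
  if (any(populations <= 0)) stop("populations must be positive")
  sum(populations * sqrt(per_state_te))^2 / sum(populations^2)
}

#' Build a group specification for the surrogate test
#'
#' @param members list of member descriptions, each a list with elements
#'   `state` (code), `population`, `effect` ([binary_series()]), `cause`
#'   ([binary_series()]) and optionally `conds` (list of [binary_series()]).
#' @return a `group_spec` object.
#' @export
group_spec <- function(members) {
  if (!length(members)) stop("a group needs at least one member")
  for (m in members) {
    check_aligned(m$effect, m$cause)
    for (s in m$conds %||% list()) check_aligned(m$effect, s)
    if (is.null(m$population) || m$population <= 0) {
      stop("member '", m$state %||% "?", "' needs a positive population")
    }
  }
  structure(list(members = members), class = "group_spec")
}

#' Permutation surrogate test of group-level conditional transfer entropy
#'
#' The observed statistic aggregates per-state conditional transfer entropy
#' with [aggregate_group_te()]. Each of the `B` surrogate replicates applies
#' an independent stratified permutation ([stratified_permute()]) to every
#' member state's cause series — strata are state-specific since they involve
#' the state's own effect series — recomputes each per-state value and
#' aggregates identically. The p-value is `#\{surrogate >= observed\} / B`
#' (reported as `"< 1/B"` when zero) and `q95` is the empirical 95% quantile
#' of the surrogate distribution.
#'
#' Permutation streams are derived deterministically from `(seed, state)` and
#' consumed replicate-by-replicate, so results are bit-reproducible and
#' invariant to the ordering of members.
#'
#' @param group a [group_spec()].
#' @param B number of surrogate replicates (study default 20000; reduced,
#'   scaled-down values >= 200 are used in tests).
#' @param seed master integer seed.
#' @param min_samples_per_cell,strict capacity guard, see
#'   [conditional_transfer_entropy()].
#' @return a `surrogate_result`: list with `observed`, `surrogate_values`,
#'   `q95`, `p_value`, `p_label`, `B`, `seed`, `per_state` (observed per-state
#'   values) and `degenerate` (codes of members with a constant cause or
#'   effect, which contribute zero TE by construction).
#' @export
surrogate_test <- function(group, B = 20000, seed = 1,
                           min_samples_per_cell = 5, strict = FALSE) {
  stopifnot(inherits(group, "group_spec"))
  if (B < 1) stop("B must be >= 1")
  members <- group$members
  codes <- vapply(seq_along(members), function(i)
    members[[i]]$state %||% as.character(i), character(1))
  pops <- vapply(members, function(m) as.numeric(m$population), numeric(1))

  prep <- lapply(members, function(m) {
    T <- length(m$effect)
    n <- T - 1L
    conds <- m$conds %||% list()
    q <- length(conds)
    check_capacity(n, q, min_samples_per_cell, strict)
    y <- unclass(m$effect)
    z <- encode_conds(conds, n)
    nz <- if (q) 2L^q else 1L
    strata <- if (is.null(z)) y[-T] else y[-T] * nz + z
    list(y1 = y[-1L], y0 = y[-T], x0 = unclass(m$cause)[-T],
         z = z, nz = nz,
         idx = split(seq_len(n), strata),
         degenerate = length(unique(unclass(m$cause))) < 2L ||
                      length(unique(y)) < 2L)
  })

  obs_state <- vapply(prep, function(p)
    cte_codes(p$y1, p$y0, p$x0, p$z, p$nz), numeric(1))
  names(obs_state) <- codes
  observed <- aggregate_group_te(obs_state, stats::setNames(pops, codes))

  # per-state surrogate matrix, one deterministic stream per member
  surr_state <- matrix(0, nrow = B, ncol = length(members))
  for (i in seq_along(members)) {
    p <- prep[[i]]
    set.seed(mix_seed(seed, codes[i]))
    for (b in seq_len(B)) {
      xs <- permute_within(p$x0, p$idx)
      surr_state[b, i] <- cte_codes(p$y1, p$y0, xs, p$z, p$nz)
    }
  }
  wt <- pops / sqrt(sum(pops^2))
  surrogate_values <- as.numeric((surr_state %^.5% wt))
  q95 <- stats::quantile(surrogate_values, 0.95, names = FALSE)
  p_value <- mean(surrogate_values >= observed - 1e-12)
  structure(list(observed = observed,
                 surrogate_values = surrogate_values,
                 q95 = q95,
                 p_value = p_value,
                 p_label = if (p_value == 0) paste0("< ", format(1 / B)) else
                   format(p_value),
                 B = B, seed = seed,
                 per_state = obs_state,
                 degenerate = codes[vapply(prep, `[[`, logical(1),
                                           "degenerate")]),
            class = "surrogate_result")
}

# row-wise aggregate: (M^0.5 %*% w)^2 for the weighted root-TE sum
`%^.5%` <- function(m, w) (sqrt(m) %*% w)^2

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf("observed TE = %.4f bits (q95 = %.4f), p %s [B = %d, seed = %d]\n",
              x$observed, x$q95,
              if (x$p_value == 0) x$p_label else paste("=", x$p_label),
              x$B, x$seed))
  if (length(x$degenerate)) {
    cat("degenerate members (constant cause or effect):",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Significance call at level alpha
#'
#' The null of no influence is rejected when `p_value < alpha` (strict
#' inequality, so `p = alpha` is not significant).
#'
#' @param result a `surrogate_result`.
#' @param alpha significance level (study value 0.050).
#' @return logical flag.
#' @export
significance <- function(result, alpha = 0.050) {
  stopifnot(inherits(result, "surrogate_result"))
  result$p_value < alpha
}
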