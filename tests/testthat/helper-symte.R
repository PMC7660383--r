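# shared test utilities

# terse binary_series constructor starting 1999-01
bs <- function(x, id = NULL) binary_series(x, start = "1999-01", id = id)

# random binary series of length T under the current RNG
rbs <- function(T, id = NULL) bs(stats::rbinom(T, 1L, 0.5), id = id)

# joint histogram counts as a plain named vector for comparisons
hist_counts <- function(effect, cause, conds = list()) {
  h <- build_joint_histogram(effect, cause, conds)
  h$counts[order(names(h$counts))]
}

# naive brute-force 1-D two-means: try every threshold, recompute WSS with
# plain means (independent of the cumulative-sum implementation under test)
brute_two_means_all <- function(x) {
  xs <- sort(unique(x))
  thr <- (xs[-length(xs)] + xs[-1]) / 2
  wss <- vapply(thr, function(th) {
    lo <- x[x < th]; hi <- x[x > th]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  list(thresholds = thr, wss = wss)
}

brute_two_means <- function(x) {
  b <- brute_two_means_all(x)
  ifelse(x > b$thresholds[which.min(b$wss)], "restrictive", "permissive")
}

# WSS achieved by a labelling
wss_of <- function(x, lab) {
  sum(vapply(unique(lab), function(g) {
    v <- x[lab == g]
    sum((v - mean(v))^2)
  }, numeric(1)))
}
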