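# Plug-in entropy, transfer entropy, conditional transfer entropy, and the
# exact-pmf oracle.

test_that("plugin_entropy matches hand-evaluated values and bounds", {
  expect_equal(plugin_entropy(c(up = 5, down = 5)), 1.0)
  expect_equal(plugin_entropy(c(up = 10, down = 0)), 0.0)
  expect_equal(plugin_entropy(c(a = 1, b = 1, c = 2)), 1.5)
  expect_error(plugin_entropy(numeric(0)), "empty")
  expect_error(plugin_entropy(c(0, 0)), "empty")
  expect_error(plugin_entropy(c(-1, 2)), "nonnegative")
  set.seed(11)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    cnt <- stats::rpois(k, 5) + (i %% 2)  # allow zero cells
    if (sum(cnt) == 0) next
    h <- plugin_entropy(cnt)
    expect_gte(h, 0)
    expect_lte(h, log2(k) + 1e-12)
  }
  # equality at extremes: degenerate iff 0, uniform iff max
  expect_equal(plugin_entropy(rep(3, 8)), 3)
  expect_gt(plugin_entropy(c(7, 1)), 0)
  expect_lt(plugin_entropy(c(7, 1)), 1)
})

test_that("build_joint_histogram tallies one transition tuple per month pair", {
  h <- build_joint_histogram(bs(c(0, 1)), bs(c(1, 1)))
  expect_equal(h$counts, c("1,0,1" = 1L))
  expect_equal(h$arity, 3L)
  h2 <- build_joint_histogram(bs(c(0, 1, 0)), bs(c(1, 0, 1)))
  expect_equal(h2$counts[order(names(h2$counts))],
               c("0,1,0" = 1L, "1,0,1" = 1L))
  set.seed(7)
  for (i in 1:20) {
    T <- sample(5:60, 1)
    q <- sample(0:2, 1)
    h <- build_joint_histogram(rbs(T), rbs(T),
                               conds = replicate(q, rbs(T), simplify = FALSE))
    expect_equal(sum(h$counts), T - 1L)
    expect_equal(h$arity, q + 3L)
  }
  expect_error(build_joint_histogram(bs(c(0, 1, 0)), bs(c(1, 0))),
               "not aligned")
  expect_error(
    build_joint_histogram(bs(c(0, 1)), binary_series(c(0, 1), start = "2000-01")),
    "not aligned")
})

test_that("transfer entropy: copy process, constant and self-predicted effects", {
  # exact oracle on the copy-process pmf
  expect_equal(te_from_pmf(coupled_pmf(1)), 1.0)
  # constant effect: H(Y(t+1)|Y(t)) is already zero
  set.seed(3)
  expect_equal(transfer_entropy(rbs(60), bs(rep(1, 60)))$value, 0)
  # deterministic alternation is fully self-predicted
  expect_equal(transfer_entropy(rbs(60), bs(rep(c(0, 1), 30)))$value, 0)
})

test_that("conditional TE with empty conditioning equals plain TE bit-for-bit", {
  set.seed(19)
  for (i in 1:20) {
    x <- rbs(60); y <- rbs(60)
    expect_identical(conditional_transfer_entropy(x, y, list())$value,
                     transfer_entropy(x, y)$value)
  }
})

test_that("TE estimates are nonnegative and invariant to symbol relabeling", {
  set.seed(23)
  for (i in 1:30) {
    T <- sample(20:120, 1)
    x <- rbs(T); y <- rbs(T); z <- rbs(T)
    v <- conditional_transfer_entropy(x, y, list(z),
                                      min_samples_per_cell = 0)$value
    expect_gte(v, 0)
    flip <- function(s) bs(1L - as.integer(s))
    v2 <- conditional_transfer_entropy(flip(x), flip(y), list(flip(z)),
                                       min_samples_per_cell = 0)$value
    expect_equal(v2, v)
  }
})

test_that("capacity guard warns at the 5-per-cell floor and errors when strict", {
  T <- 50  # 49 transitions < 5 * 2^4 = 80 cells-worth for q = 1
  set.seed(5)
  x <- rbs(T); y <- rbs(T); z <- rbs(T)
  expect_warning(conditional_transfer_entropy(x, y, list(z)), "capacity")
  expect_error(conditional_transfer_entropy(x, y, list(z), strict = TRUE),
               "capacity")
  expect_silent(conditional_transfer_entropy(x, y, list()))
})

test_that("te_from_pmf: exact values, normalization check, histogram consistency", {
  unif <- expand.grid(y_next = 0:1, y_now = 0:1, x_now = 0:1)
  unif$prob <- 1 / 8
  expect_equal(te_from_pmf(unif), 0)
  expect_equal(te_from_pmf(coupled_pmf(1)), 1)
  bad <- unif; bad$prob <- bad$prob * 2
  expect_error(te_from_pmf(bad), "not normalized")
  set.seed(31)
  x <- rbs(300); y <- rbs(300); z <- rbs(300)
  h <- build_joint_histogram(y, x, list(z))
  expect_equal(te_from_pmf(histogram_pmf(h)),
               conditional_transfer_entropy(x, y, list(z))$value)
})

test_that("confounder chain: pairwise TE positive, conditional TE zero (exact)", {
  # persistent driver (see vignette: an iid driver makes both vanish at lag 1)
  expect_gt(te_from_pmf(confounded_pmf(0.9, include_z = FALSE)), 0.1)
  expect_equal(te_from_pmf(confounded_pmf(0.9, include_z = TRUE)), 0)
  # independent extra conditioning leaves TE unchanged (exact pmf)
  g <- coupled_pmf(0.5)
  gz <- merge(g, data.frame(z = 0:1))
  gz$prob <- gz$prob / 2
  expect_equal(te_from_pmf(gz[c("y_next", "y_now", "x_now", "z", "prob")]),
               te_from_pmf(g))
})

test_that("plug-in estimates converge to the exact-pmf oracle", {
  g <- gen_coupled_binary(10000, coupling = 0.5, seed = 41)
  expect_lt(abs(conditional_transfer_entropy(g$cause, g$effect)$value -
                  te_from_pmf(coupled_pmf(0.5))), 0.02)
  tr <- gen_confounded_triplet(10000, seed = 43)
  expect_lt(abs(transfer_entropy(tr$x, tr$y)$value -
                  te_from_pmf(confounded_pmf(0.9, include_z = FALSE))), 0.02)
  expect_lt(conditional_transfer_entropy(tr$x, tr$y, list(tr$z))$value, 0.02)
})

test_that("histogram JSON export round-trips the counts", {
  set.seed(47)
  h <- build_joint_histogram(rbs(50), rbs(50))
  js <- jsonlite::fromJSON(histogram_to_json(h))
  expect_equal(js$n, 49)
  expect_equal(unlist(js$counts), unlist(as.list(h$counts)))
})
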