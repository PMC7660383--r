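# Stratified permutation, group aggregation, surrogate test, significance.

test_that("stratified permutation: identity, global shuffle, admissible set", {
  x <- bs(c(1, 0, 0, 1, 1))
  # singleton strata: nothing can move
  set.seed(1)
  expect_identical(as.integer(stratified_permute(x, strata = 1:4)),
                   as.integer(x))
  # one global stratum: a permutation of the first T-1 values
  set.seed(2)
  p <- stratified_permute(x, strata = rep(1, 4))
  expect_equal(sort(as.integer(p)[1:4]), sort(as.integer(x)[1:4]))
  expect_equal(as.integer(p)[5], 1L)
  # strata {t1, t3} and {t2, t4} over the four transition times with cause
  # symbols [up, down, down, up]: admissible outputs swap only within a stratum
  x5 <- bs(c(1, 0, 0, 1, 1))
  admissible <- c("1001", "0011", "1100", "0110")
  seen <- character(0)
  set.seed(3)
  for (i in 1:200) {
    out <- as.integer(stratified_permute(x5, strata = c(1, 2, 1, 2)))
    expect_equal(out[5], 1L)  # final symbol enters no transition sample
    key <- paste(out[1:4], collapse = "")
    expect_true(key %in% admissible)
    seen <- union(seen, key)
  }
  expect_setequal(seen, admissible)  # all admissible permutations occur
  expect_error(stratified_permute(x, strata = 1:3), "T - 1")
})

test_that("stratified permutation preserves the (X, Y, Z) joint histogram", {
  set.seed(7)
  for (i in 1:100) {
    T <- sample(10:80, 1)
    x <- rbs(T); y <- rbs(T); z <- rbs(T)
    n <- T - 1L
    strata <- paste(as.integer(y)[-T], as.integer(z)[-T])
    xp <- stratified_permute(x, strata)
    before <- table(paste(as.integer(x)[-T], strata))
    after <- table(paste(as.integer(xp)[-T], strata))
    expect_identical(before, after)
  }
})

test_that("population-weighted aggregation follows the stated formula", {
  expect_equal(aggregate_group_te(c(A = 0.37), c(A = 9e6)), 0.37)
  expect_equal(aggregate_group_te(c(A = 0, B = 0), c(A = 1e6, B = 2e6)), 0)
  # two states, equal populations, TE = 0.09 each: (2p*0.3)^2 / (2p^2) = 0.18
  expect_equal(aggregate_group_te(c(A = 0.09, B = 0.09), c(A = 5, B = 5)),
               0.18)
  set.seed(9)
  te <- runif(6); pop <- stats::setNames(runif(6, 1, 10), letters[1:6])
  names(te) <- letters[1:6]
  expect_equal(aggregate_group_te(te, pop * 1e4), aggregate_group_te(te, pop))
  # reordering the named vectors does not matter
  expect_equal(aggregate_group_te(te[c(3, 1, 2, 6, 5, 4)], pop),
               aggregate_group_te(te, pop))
  expect_error(aggregate_group_te(c(A = -0.1), c(A = 1)), "negative")
  expect_error(aggregate_group_te(c(A = 0.1), c(B = 1)), "keys")
  expect_error(aggregate_group_te(c(A = 0.1), c(A = 0)), "positive")
})

test_that("surrogate test: planted coupling is detected, B = 1 degenerates sanely", {
  g <- gen_coupled_binary(228, coupling = 1, seed = 11)
  grp <- group_spec(list(list(state = "A", population = 1e6,
                              effect = g$effect, cause = g$cause)))
  res <- surrogate_test(grp, B = 200, seed = 5)
  expect_lte(res$p_value, 0.005)
  expect_match(res$p_label, "< 0.005")
  expect_true(significance(res))
  expect_equal(res$observed, transfer_entropy(g$cause, g$effect)$value)
  expect_equal(res$q95,
               stats::quantile(res$surrogate_values, 0.95, names = FALSE))
  r1 <- surrogate_test(grp, B = 1, seed = 5)
  expect_length(r1$surrogate_values, 1L)
  expect_true(r1$p_value %in% c(0, 1))
})

test_that("surrogate test is reproducible and member-order invariant", {
  set.seed(21)
  members <- lapply(1:4, function(i) {
    list(state = LETTERS[i], population = 10^runif(1, 5, 7),
         effect = rbs(120), cause = rbs(120), conds = list(rbs(120)))
  })
  a <- surrogate_test(group_spec(members), B = 50, seed = 77)
  b <- surrogate_test(group_spec(members), B = 50, seed = 77)
  expect_identical(a$surrogate_values, b$surrogate_values)
  shuffled <- surrogate_test(group_spec(members[c(3, 1, 4, 2)]), B = 50,
                             seed = 77)
  expect_equal(shuffled$observed, a$observed)
  expect_equal(sort(names(shuffled$per_state)), sort(names(a$per_state)))
  expect_equal(shuffled$surrogate_values, a$surrogate_values)
  different <- surrogate_test(group_spec(members), B = 50, seed = 78)
  expect_false(identical(different$surrogate_values, a$surrogate_values))
})

test_that("degenerate members are flagged and contribute zero", {
  g <- gen_coupled_binary(100, coupling = 0, seed = 31)
  grp <- group_spec(list(
    list(state = "A", population = 1, effect = g$effect, cause = g$cause),
    list(state = "Z", population = 1, effect = g$effect,
         cause = bs(rep(0, 100)))))
  res <- surrogate_test(grp, B = 20, seed = 1)
  expect_equal(res$degenerate, "Z")
  expect_equal(unname(res$per_state["Z"]), 0)
})

test_that("significance uses a strict threshold", {
  fake <- function(p) structure(list(p_value = p), class = "surrogate_result")
  expect_true(significance(fake(0.002)))
  expect_false(significance(fake(0.050)))
  expect_false(significance(fake(0.954)))
})
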