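test_that("chisq_gof reproduces hand-computed statistics", {
  r <- chisq_gof(c(a = 60, b = 40), c(a = 0.5, b = 0.5))
  expect_equal(r$statistic, 4) # (10^2/50) + (10^2/50)
  expect_equal(r$df, 1L)

  r2 <- chisq_gof(c(a = 10, b = 20, c = 30), c(a = 1, b = 1, c = 1) / 3)
  expect_equal(r2$statistic, 10) # (100 + 0 + 100)/20
  expect_equal(r2$df, 2L)

  # observed proportional to expected: statistic 0, p exactly 1
  r3 <- chisq_gof(c(a = 50, b = 50), c(a = 0.5, b = 0.5))
  expect_identical(r3$statistic, 0)
  expect_identical(r3$p_value, 1)

  expect_error(chisq_gof(c(a = 1), c(b = 1)), "mismatch")
  expect_error(chisq_gof(c(a = 1, b = 0), c(a = 0, b = 1)), "zero expected")
})

test_that("chisq_gof agrees with stats::chisq.test on random tables", {
  set.seed(55)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    freq <- as.numeric(rmultinom(1, 60, rep(1, k)) + 1)
    freq <- freq / sum(freq)
    names(freq) <- letters[seq_len(k)]
    O <- setNames(as.numeric(rmultinom(1, 200, freq)), names(freq))
    r <- chisq_gof(O, freq)
    ref <- suppressWarnings(stats::chisq.test(O, p = freq))
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(r$p_value, unname(ref$p.value), tolerance = 1e-9)
    expect_equal(sum(r$per_category_contributions), r$statistic)
  }
})

test_that("aggregate_eu_het partitions the standard categories", {
  expect_equal(
    aggregate_eu_het(c(A = 10, XL = 2, XR = 3, Fourth = 5, Y = 4)),
    c(Eu = 12, Het = 12)
  )
  expect_equal(
    aggregate_eu_het(c(A = 0, XL = 0, XR = 0, Fourth = 0, Y = 0)),
    c(Eu = 0, Het = 0)
  )
  expect_error(aggregate_eu_het(c(A = 1, Z = 2)), "unknown categories")
})

test_that("ring_excess_test equals the brute-force binomial tail", {
  tail_sum <- function(k, n, p) sum(dbinom(k:n, n, p)) # independent oracle
  r <- ring_excess_test(30, 27, 1 / 15)
  expect_equal(r$p_value, tail_sum(27, 30, 1 / 15), tolerance = 1e-12)

  set.seed(77)
  for (i in 1:25) {
    n <- sample(1:60, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.01, 0.5)
    expect_equal(
      ring_excess_test(n, k, p0)$p_value,
      tail_sum(k, n, p0),
      tolerance = 1e-12
    )
  }

  # observed at expectation: p in the mid-range
  r2 <- ring_excess_test(30, 2, 1 / 15)
  expect_equal(r2$observed_fraction, 1 / 15)
  expect_gt(r2$p_value, 0.2)
  expect_lt(r2$p_value, 0.9)

  r3 <- ring_excess_test(0, 0, 1 / 15)
  expect_identical(r3$p_value, 1)
  expect_true(r3$degenerate)
  expect_error(ring_excess_test(5, 6, 1 / 15), "y_ring_count")
})

test_that("the generative frequency model matches the null at w = 1", {
  types <- telofuse:::.bias_types(male_kar)
  q <- telofuse:::.expected_category_freq(types, 1, mean_events = 1)
  freq <- expected_involvement_frequencies(male_kar)
  expect_equal(q[names(freq)], freq, tolerance = 1e-12)
  # and for the single-event model too
  q1 <- telofuse:::.expected_category_freq(types, 1, mean_events = NULL)
  expect_equal(q1[names(freq)], freq, tolerance = 1e-12)
})

test_that("the generative frequency model matches Monte Carlo at w = 3", {
  types <- telofuse:::.bias_types(male_kar)
  q <- telofuse:::.expected_category_freq(types, 3, mean_events = 1)
  ct <- simulate_experiment(male_kar, bias_model(het_weight = 3), 8000,
    seed = 21)
  emp <- ct$counts / sum(ct$counts)
  se <- sqrt(q[names(emp)] * (1 - q[names(emp)]) / sum(ct$counts))
  expect_true(all(abs(emp - q[names(emp)]) <= 3 * se))
})

test_that("estimate_bias recovers the null weight and flags degenerate data", {
  ct <- simulate_experiment(male_kar, bias_model(), 2000, seed = 5)
  est <- estimate_bias(ct, male_kar, n_boot = 300, seed = 1)
  expect_false(est$capped)
  expect_true(est$converged)
  expect_lte(est$ci_low, 1)
  expect_gte(est$ci_high, 1)
  expect_lte(est$ci_low, est$w_hat)
  expect_gte(est$ci_high, est$w_hat)

  # all counts in the heterochromatic group: estimate pinned at the cap
  degen <- count_table(c(A = 0, XL = 0, XR = 12, Fourth = 20, Y = 8))
  ed <- estimate_bias(degen, male_kar, method = "single_event", n_boot = 0)
  expect_true(ed$capped)
  expect_equal(ed$w_hat, 1e6)

  expect_error(
    estimate_bias(count_table(c(A = 0, XL = 0)), male_kar, n_boot = 0),
    "positive total"
  )
})

test_that("single_event method is exposed and falls back when cells are unknown", {
  ct <- simulate_experiment(male_kar, bias_model(het_weight = 2), 1500,
    seed = 8)
  e1 <- estimate_bias(ct, male_kar, method = "single_event", n_boot = 0)
  expect_false(e1$capped)
  expect_gt(e1$w_hat, 1)
  # a bare table without cell counts silently uses the single-event model
  bare <- count_table(ct$counts)
  e2 <- estimate_bias(bare, male_kar, n_boot = 0)
  expect_equal(e2$method, "single_event")
  expect_equal(e2$w_hat, e1$w_hat, tolerance = 1e-8)
})
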