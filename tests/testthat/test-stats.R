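test_that("a_test matches direct pair enumeration on worked examples", {
  expect_equal(a_test(c(1, 1, 1), c(1, 1, 1))$score, 0.5)
  expect_equal(a_test(c(2, 3), c(0, 1))$score, 1.0)
  # one strict win (3 > 2), two ties over 9 pairs
  expect_equal(a_test(c(1, 2, 3), c(2, 3, 4))$score, 2 / 9)
  expect_error(a_test(numeric(0), 1), "non-empty")
})

test_that("a_test equals the brute-force oracle on random samples", {
  set.seed(42)
  for (i in 1:25) {
    n1 <- sample(1:30, 1)
    n2 <- sample(1:30, 1)
    # integer-valued draws force plenty of ties
    x <- sample(0:5, n1, replace = TRUE) + ifelse(i %% 2 == 0, 0, 0.5)
    y <- sample(0:5, n2, replace = TRUE)
    expect_equal(a_test(x, y)$score, a_test_bruteforce(x, y),
                 tolerance = 1e-12)
  }
})

test_that("a_test is complementary and translation invariant", {
  set.seed(7)
  for (i in 1:20) {
    x <- rpois(sample(2:20, 1), 5)
    y <- rpois(sample(2:20, 1), 6)
    s_xy <- a_test(x, y)$score
    expect_equal(s_xy + a_test(y, x)$score, 1)
    expect_equal(a_test(x + 13.7, y + 13.7)$score, s_xy)
  }
})

test_that("classify_effect reproduces the published score-label pairings", {
  expect_equal(classify_effect(0.999), "large")
  expect_equal(classify_effect(0.163), "large")
  expect_equal(classify_effect(0.090), "large")
  expect_equal(classify_effect(0.704), "medium")
  # reported as showing no real scientific significance: not large
  expect_false(classify_effect(0.503) == "large")
  expect_false(classify_effect(0.427) == "large")
  expect_false(classify_effect(0.635) == "large")
  expect_equal(classify_effect(0.5), "none")
  # band edges resolve to the larger class
  expect_equal(classify_effect(c(0.71, 0.29)), c("large", "large"))
  expect_equal(classify_effect(c(0.64, 0.36)), c("medium", "medium"))
  expect_equal(classify_effect(c(0.56, 0.44)), c("small", "small"))
  expect_error(classify_effect(1.2), "0, 1")
})

test_that("median_curve takes pointwise medians with midpoint even-n rule", {
  runs3 <- lapply(c(1, 2, 9), function(v) make_run(rep(v, 5)))
  mc <- median_curve(make_ensemble(runs3), "CD8Treg")
  expect_equal(mc$median_count, rep(2, 5))
  # even n: midpoint of central order statistics
  runs4 <- lapply(c(5, 7, 9, 11), function(v) make_run(rep(v, 3)))
  mc4 <- median_curve(make_ensemble(runs4), "CD8Treg")
  expect_equal(mc4$median_count, rep(8, 3))
  # a single run is its own median curve
  one <- make_run(c(0, 3, 8, 2))
  expect_equal(median_curve(make_ensemble(list(one)), "CD8Treg")$median_count,
               c(0, 3, 8, 2))
  # cadence mismatch is an error
  bad <- make_ensemble(list(make_run(1:4), make_run(1:5)))
  expect_error(median_curve(bad, "CD8Treg"), "cadence")
})

test_that("peak_population returns per-run maxima over summed compartments", {
  rise_fall <- make_run(c(0, 4, 9, 6, 1))
  flat_zero <- make_run(rep(0, 5))
  ens <- make_ensemble(list(rise_fall, flat_zero))
  expect_equal(peak_population(ens, "CD8Treg"), c(9, 0))
  # counts in different compartments are summed before the maximum
  a <- make_run(c(1, 5, 2), compartment = "Spleen")
  a$counts[, "CD8Treg", "effector", "CLN"] <- c(4, 4, 0)
  expect_equal(peak_population(make_ensemble(list(a)), "CD8Treg"), 9)
})
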