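test_that("paired bootstrap t handles null, shift and error contracts", {
  set.seed(1)
  a <- rnorm(16)
  same <- paired_bootstrap_t(a, a, seed = 1)
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  expect_gt(same$p, 0.9)

  shifted <- paired_bootstrap_t(a + 1, a, n_boot = 2000, seed = 2)
  expect_lt(shifted$p, 0.01)
  expect_true(shifted$ci_low <= shifted$ci_high)
  expect_equal(shifted$d, abs(shifted$t) / 4)

  expect_error(paired_bootstrap_t(1:5, 1:4), class = "LengthMismatch")
  expect_error(paired_bootstrap_t(1:2, 2:3), class = "TooFewPairs")
})

test_that("paired test has power ~ stated at the Bonferroni threshold", {
  # delta = 1, sigma = 1, n = 16: rejection rate at alpha = 0.007 >= 0.8
  # the shift applies to the paired differences: a - b ~ N(1, 1)
  set.seed(99)
  rejections <- vapply(1:200, function(r) {
    b <- rnorm(16)
    a <- b + rnorm(16, mean = 1, sd = 1)
    paired_bootstrap_t(a, b, n_boot = 500, seed = r)$p < 0.007
  }, logical(1))
  expect_gte(mean(rejections), 0.8)
})

test_that("independent bootstrap t matches a closed-form oracle for d", {
  set.seed(4)
  a <- rnorm(675, 20.77, 15)
  b <- rnorm(47, 15.21, 15)
  r <- independent_bootstrap_t(a, b, seed = 4)
  # oracle: pooled-SD standardised difference computed from first principles
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  expect_equal(r$d, abs(mean(a) - mean(b)) / sp, tolerance = 1e-12)
  expect_lt(r$p, 0.05)

  same <- independent_bootstrap_t(a, a, seed = 5)
  expect_equal(same$d, 0)
  expect_gt(same$p, 0.9)

  # equal means, unequal variances: Welch t near 0
  set.seed(6)
  w <- independent_bootstrap_t(rnorm(400, 0, 1), rnorm(400, 0, 6), seed = 6)
  expect_lt(abs(w$t), 2.5)

  expect_error(independent_bootstrap_t(1, 1:5), class = "TooFewValues")
})

test_that("bonferroni threshold is alpha over m", {
  expect_equal(round(bonferroni_alpha(0.05, 7), 3), 0.007)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
})

test_that("permutation test: null identity, extreme case, validity bound", {
  set.seed(11)
  x <- rnorm(16)
  same <- permutation_test(x, sample(x), n_perm = 999, seed = 1)
  expect_gt(same$p, 0.5)

  far <- permutation_test(rnorm(16, 100, 0.1), rnorm(16, 0, 0.1),
                          n_perm = 999, seed = 2)
  expect_equal(far$p, 1 / 1000)  # add-one lower bound attained

  r <- permutation_test(rnorm(10), rnorm(12), n_perm = 499, seed = 3)
  expect_true(r$p >= 1 / 500 && r$p <= 1)

  expect_error(permutation_test(rep(1, 5), rep(1, 5)),
               class = "DegenerateGroups")
  expect_error(permutation_test(numeric(0), 1:3), class = "TooFewValues")
})

test_that("bootstrap and classical p agree in rank order on shift families", {
  set.seed(21)
  base <- rnorm(16)
  shifts <- c(0.1, 0.3, 0.6, 1.0)
  noise <- rnorm(16)
  noise <- noise - mean(noise)  # keep the realised shift equal to s
  ps <- vapply(shifts, function(s)
    paired_bootstrap_t(base + s + noise, base, n_boot = 4000, seed = 7)$p,
    numeric(1))
  pc <- vapply(shifts, function(s)
    paired_bootstrap_t(base + s + noise, base, seed = 7)$p_classical,
    numeric(1))
  expect_true(all(diff(pc) < 0))
  expect_true(all(diff(ps) <= 0))
  expect_gt(cor(rank(ps), rank(pc)), 0.8)
})

test_that("au_comparison_table pairs participants and applies the threshold", {
  summaries <- cohort_mean_aus(small_cohort())
  tab <- au_comparison_table(summaries, n_boot = 300, seed = 2)
  expect_equal(nrow(tab), 7)
  expect_equal(attr(tab, "alpha_bonferroni"), 0.05 / 7)
  expect_true(all(tab$ci_low <= tab$ci_high))
  expect_true(all(tab$d >= 0))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
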