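test_that("transition moments match the closed-form birth-death solution", {
  # hand-computed: n1 = 100, s = 0.1, lambda = 1, dt = 5
  # mean = 100 * e^0.5; var = 100 * (2.1 / 0.1) * e^0.5 * (e^0.5 - 1)
  tr <- clone_transition(100, s = 0.1, lambda = 1, dt = 5)
  expect_equal(tr$mean, 100 * exp(0.5))
  expect_equal(tr$variance, 100 * 21 * exp(0.5) * (exp(0.5) - 1))
  expect_identical(tr$family, "negative_binomial")
  # NB parameters moment-match
  m <- tr$mean
  v <- tr$variance
  expect_equal(tr$size, m^2 / (v - m))
  expect_equal(tr$prob, m / v)
  expect_equal(tr$size * (1 - tr$prob) / tr$prob, m)
  expect_equal(tr$size * (1 - tr$prob) / tr$prob^2, v)
})

test_that("neutral clones are a martingale with linear variance growth", {
  tr <- clone_transition(250, s = 0, lambda = 1, dt = 7)
  expect_equal(tr$mean, 250)
  expect_equal(tr$variance, 2 * 1 * 250 * 7)
})

test_that("variance is continuous at s = 0", {
  v0 <- clone_transition(100, s = 0, lambda = 1, dt = 3)$variance
  veps <- clone_transition(100, s = 1e-9, lambda = 1, dt = 3)$variance
  expect_equal(veps, v0, tolerance = 1e-6)
})

test_that("negative fitness shrinks the mean and keeps variance positive", {
  tr <- clone_transition(100, s = -0.1, lambda = 1, dt = 12)
  expect_equal(tr$mean, 100 * exp(-1.2))
  expect_gt(tr$variance, 0)
})

test_that("degenerate transitions are point masses", {
  expect_identical(clone_transition(100, 0.1, 1, 0)$family, "point_mass")
  expect_identical(clone_transition(0, 0.1, 1, 5)$family, "point_mass")
  expect_equal(clone_transition(0, 0.1, 1, 5)$mean, 0)
})

test_that("clone_transition validates inputs", {
  expect_error(clone_transition(-1, 0.1, 1, 1))
  expect_error(clone_transition(10, 0.1, 1, -1))
  expect_error(clone_transition(10, -2, 1, 1))   # s < -lambda
  expect_error(clone_transition(10, 0.1, 0, 1))  # lambda <= 0
})

test_that("VAF map and its inverse round-trip", {
  v <- vaf_from_counts(c(1e4, 2e4), n_w = 1e5)
  expect_equal(v, c(1e4, 2e4) / (2 * (1e5 + 3e4)))
  expect_true(all(v >= 0 & v < 0.5))
  # single-clone inverse
  n <- 5e3
  v1 <- vaf_from_counts(n, 1e5)
  expect_equal(clone_size_from_vaf(v1, 1e5), n)
  expect_equal(clone_size_from_vaf(0, 1e5), 0)
  expect_error(clone_size_from_vaf(0.5, 1e5))
  expect_error(vaf_from_counts(-1, 1e5))
})

test_that("sampling log likelihood is a normalised binomial", {
  # sums to 1 over alt = 0..depth (depth = 50 grid check)
  for (v in c(0, 0.013, 0.37, 1)) {
    expect_equal(sum(exp(sampling_loglik(0:50, 50, v))), 1)
  }
  expect_error(sampling_loglik(51, 50, 0.1))
  expect_error(sampling_loglik(5, 50, 1.2))
})

test_that("deterministic VAF curve has the right anchors", {
  n_w <- 1e5
  s <- 0.15
  t0 <- 40
  expect_equal(deterministic_vaf(t0, s, n_w, t0), 1 / (2 + 2 * n_w))
  expect_equal(deterministic_vaf(t0 + 1e4, s, n_w, t0), 0.5,
               tolerance = 1e-6)
  # quarter point at t0 + ln(N_w)/s
  expect_equal(deterministic_vaf(t0 + log(n_w) / s, s, n_w, t0), 0.25)
  expect_true(all(diff(deterministic_vaf(40:90, s, n_w, t0)) > 0))
})

test_that("acquisition time is recovered from noiseless logistic data", {
  n_w <- 1e5
  s <- 0.15
  t0 <- 40
  ages <- seq(70, 82, 3)
  depth <- rep(2000, length(ages))
  alt <- round(depth * deterministic_vaf(ages, s, n_w, t0))
  est <- fit_t0_mle(ages, alt, depth, s, n_w)
  # within the resolution of the 512-point bracketing grid
  expect_lt(abs(est - t0), (200 / 511) * 2)
})

test_that("fit_t0_mle validates inputs", {
  expect_error(fit_t0_mle(c(70, 73), c(1, 2), c(10, 10), s = 0, n_w = 1e5))
})
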