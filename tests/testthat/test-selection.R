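test_that("forward_freq fixed points and monotonicity", {
  for (m in c("simple", "dominance", "additive")) {
    expect_equal(forward_freq(0.3, 0, 15, m), 0.3)   # neutral fixed point
    expect_equal(forward_freq(0, 0.1, 15, m), 0)     # absorbing state
  }
  # strictly increasing in s for interior frequencies
  s_grid <- seq(0, 0.3, by = 0.025)
  for (m in c("simple", "dominance", "additive")) {
    traj <- vapply(s_grid, function(s) forward_freq(0.06, s, 20, m), 0)
    expect_true(all(diff(traj) > 0))
  }
  # normalized models stay within [0, 1]
  expect_lte(forward_freq(0.9, 0.5, 50, "dominance"), 1)
  expect_lte(forward_freq(0.9, 0.5, 50, "additive"), 1)
  expect_error(forward_freq(1.2, 0.1, 5), "f0")
})

test_that("dominance/additive trajectories never exceed the simple bound", {
  set.seed(4)
  for (i in 1:20) {
    f0 <- runif(1, 0.01, 0.5); s <- runif(1, 0.005, 0.2)
    n <- sample(1:30, 1)
    fs <- forward_freq(f0, s, n, "simple")
    expect_lt(forward_freq(f0, s, n, "dominance"), fs)
    expect_lt(forward_freq(f0, s, n, "additive"), fs)
  }
})

test_that("closed-form simple estimator and its guards", {
  expect_equal(round(s_simple(0.128, 0.365, 20), 3), 0.054)
  expect_equal(round(s_simple(0.079, 0.325, 20), 3), 0.073)
  # scale invariance: dosages and frequencies give the same s
  expect_equal(s_simple(0.128, 0.365, 20), s_simple(0.064, 0.1825, 20))
  expect_error(s_simple(0.3, 0.3), "exceed")
})

test_that("bisection solver matches an independent root finder", {
  for (m in c("dominance", "additive")) {
    for (row in list(c(0.128, 0.365), c(0.079, 0.325), c(0.2, 0.6))) {
      fit <- solve_s(row[1], row[2], 20, m)
      oracle <- uniroot(function(s)
        forward_freq(row[1] / 2, s, 20, m) - row[2] / 2,
        c(0, 1), tol = 1e-12)$root
      expect_equal(fit$s_hat, oracle, tolerance = 1e-5)
      expect_lt(abs(fit$residual), fit$epsilon)
    }
  }
})

test_that("solver round-trips a known coefficient", {
  p0 <- 0.15
  for (m in c("dominance", "additive")) {
    p1 <- 2 * forward_freq(p0 / 2, 0.05, 20, m)
    expect_equal(solve_s(p0, p1, 20, m)$s_hat, 0.05, tolerance = 1e-4)
  }
  # forward under the dominance model inverts the solved coefficient
  fit <- solve_s(0.128, 0.365, 20, "dominance")
  expect_equal(2 * forward_freq(0.064, fit$s_hat, 20, "dominance"), 0.365,
               tolerance = 1e-6)
})

test_that("solver input guards", {
  expect_error(solve_s(0.3, 0.2), "p0 < p1")
  expect_error(solve_s(0.5, 2, model = "dominance"), "< 1")
})
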