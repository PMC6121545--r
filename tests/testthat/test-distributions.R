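test_that("beta moment matching recovers the input moments analytically", {
  cases <- list(
    c(0.18, 0.0070), c(0.0015, 0.0004), c(0.0681, 0.0170),
    c(0.844, 0.0096), c(0.5, 0.1), c(0.283, 0.0130)
  )
  for (cs in cases) {
    sh <- beta_params_from_moments(cs[1], cs[2])
    expect_gt(sh$alpha, 0)
    expect_gt(sh$beta, 0)
    m <- sh$alpha / (sh$alpha + sh$beta)
    v <- sh$alpha * sh$beta / ((sh$alpha + sh$beta)^2 * (sh$alpha + sh$beta + 1))
    expect_equal(m, cs[1], tolerance = 1e-9)
    expect_equal(sqrt(v), cs[2], tolerance = 1e-9)
  }
})

test_that("beta fit of the anxiety probability matches the hand solution", {
  # alpha + beta = m(1-m)/se^2 - 1 = 0.18*0.82/0.0070^2 - 1 = 3011.2
  sh <- beta_params_from_moments(0.18, 0.0070)
  expect_equal(sh$alpha, 542.0, tolerance = 1e-3)
  expect_equal(sh$beta, 2469.2, tolerance = 1e-3)
})

test_that("beta fit rejects degenerate and infeasible inputs", {
  expect_error(beta_params_from_moments(0.5, 0), "se")
  expect_error(beta_params_from_moments(0, 0.1), "between 0 and 1")
  expect_error(beta_params_from_moments(1, 0.1), "between 0 and 1")
  # variance bound named in the message
  expect_error(beta_params_from_moments(0.5, 0.6), "mean\\*\\(1-mean\\)")
})

test_that("sampling from the fitted beta recovers the mean (Monte Carlo)", {
  sh <- beta_params_from_moments(0.18, 0.0070)
  draws <- withr::with_seed(101, stats::rbeta(1e6, sh$alpha, sh$beta))
  expect_lt(abs(mean(draws) - 0.18), 3 * 0.0070 / sqrt(1e6))
})

test_that("gamma moment matching is exact in closed form", {
  sh <- gamma_params_from_moments(23229, 5807)
  expect_equal(sh$shape, (23229 / 5807)^2, tolerance = 1e-12)
  expect_equal(sh$shape * sh$scale, 23229, tolerance = 1e-9)
  expect_equal(sh$shape * sh$scale^2, 5807^2, tolerance = 1e-6)
  # exponential special case
  expect_equal(gamma_params_from_moments(1, 1), list(shape = 1, scale = 1))
  expect_error(gamma_params_from_moments(-1, 1), "> 0")
  expect_error(gamma_params_from_moments(1, 0), "> 0")
})

test_that("lognormal CI fit reproduces hand arithmetic on published intervals", {
  lp <- lognormal_params_from_ci(1.14, 1.08, 1.20)
  expect_equal(lp$sigma, 0.02688, tolerance = 1e-4)
  expect_equal(lp$mu, 0.12964, tolerance = 1e-4)
  lp2 <- lognormal_params_from_ci(1.79, 1.00, 3.06)
  expect_equal(lp2$sigma, 0.28530, tolerance = 1e-4)
  # degenerate interval is a point mass
  lp3 <- lognormal_params_from_ci(1.0, 1.0, 1.0)
  expect_identical(lp3$sigma, 0)
  expect_identical(lp3$mu, 0)
  # the fitted 95% interval is exactly the printed range
  expect_equal(exp(lp$mu + stats::qnorm(0.975) * lp$sigma), 1.20, tolerance = 1e-9)
  expect_equal(exp(lp$mu - stats::qnorm(0.975) * lp$sigma), 1.08, tolerance = 1e-9)
  expect_error(lognormal_params_from_ci(1, -1, 2), "positive")
  expect_error(lognormal_params_from_ci(1, 2, 1.5), "ci_low")
  expect_error(lognormal_params_from_ci(1, 1.2, 1.5), "inside")
})

test_that("odds-ratio conversion matches hand values and bounds", {
  expect_equal(or_to_rr(1.0, 0.3), 1.0)
  expect_equal(or_to_rr(2.0, 0.115), 1.7937, tolerance = 1e-4)
  expect_equal(or_to_rr(2.0, 0.18), 1.6949, tolerance = 1e-4)
  expect_error(or_to_rr(0, 0.5), "> 0")
  expect_error(or_to_rr(2, 1), "between 0 and 1")
})

test_that("odds-ratio conversion is monotone: increasing in OR, decreasing in p0", {
  ors <- seq(1.1, 5, by = 0.3)
  p0s <- seq(0.05, 0.9, by = 0.05)
  for (p0 in p0s) {
    rr <- or_to_rr(ors, p0)
    expect_true(all(diff(rr) > 0))
    expect_true(all(rr > 1 & rr < ors))
  }
  for (or in ors) {
    rr <- or_to_rr(or, p0s)
    expect_true(all(diff(rr) < 0))
  }
})
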