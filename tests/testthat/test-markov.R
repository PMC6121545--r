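test_that("event probabilities combine base risk and multipliers, capped at 1", {
  p <- test_params()
  arms <- build_arms(p)
  expect_equal(cvd_event_prob(50, FALSE, arms$limited, p), 0.0071)
  expect_equal(
    cvd_event_prob(50, TRUE, arms$year_round, p),
    0.0071 * 1.965 * 1.14,
    tolerance = 1e-12
  )
  unit <- arm_spec("limited", 1, 1, 0)
  p1 <- set_parameters(p, rr_cvd_prior = 1)
  expect_equal(cvd_event_prob(70, TRUE, unit, p1), 0.0266)
  expect_error(cvd_event_prob(10, FALSE, unit, p), "below CVD risk coverage")

  expect_equal(anxiety_event_prob(FALSE, arms$limited, p), 0.18)
  expect_equal(anxiety_event_prob(FALSE, arms$year_round, p), 0.3222, tolerance = 1e-12)
  expect_equal(
    anxiety_event_prob(TRUE, arms$year_round, p),
    0.18 * 1.66 * 1.79,
    tolerance = 1e-12
  )
  # cap: force an absurd multiplier
  big <- arm_spec("year_round", 1, 50, 0)
  expect_equal(anxiety_event_prob(TRUE, big, p), 1)
})

test_that("cohort trace conserves occupancy and death is monotone", {
  p <- test_params()
  lt <- test_lt()
  for (arm in build_arms(p)) {
    tr <- run_cohort(p, arm, lt)
    occ <- tr$n_no_prior_cvd + tr$n_prior_cvd + tr$n_dead
    expect_true(all(abs(occ - 1) < 1e-12))
    expect_true(all(diff(tr$n_dead) >= 0))
    expect_true(all(tr$cvd_events <= tr$n_no_prior_cvd + tr$n_prior_cvd + 1e-12))
    expect_true(all(tr$qaly_disc >= 0))
    # totals equal the sum of cycle values
    tot <- discounted_totals(tr)
    expect_equal(tot$cost, sum(tr$cost_disc), tolerance = 1e-9)
    expect_equal(tot$qalys, sum(tr$qaly_disc), tolerance = 1e-9)
  }
})

test_that("degenerate reward settings behave as closed forms predict", {
  lt <- test_lt()
  p0 <- test_params(
    u_no_cvd = 0, u_prior_cvd = 0,
    disutil_cvd_event = 0, disutil_anxiety = 0
  )
  tr <- run_cohort(p0, build_arms(p0)$limited, lt)
  expect_equal(discounted_totals(tr)$qalys, 0)

  pr0 <- test_params(discount_rate = 0)
  tr0 <- run_cohort(pr0, build_arms(pr0)$year_round, lt)
  tot <- discounted_totals(tr0)
  expect_equal(tot$cost, tot$cost_undisc, tolerance = 1e-9)
  expect_equal(tot$qalys, tot$qalys_undisc, tolerance = 1e-9)
})

test_that("arms are identical when exposure carries no risk and no cost", {
  p <- test_params(
    rr_cvd_noise = 1, rr_anx_noise = 1,
    exposure_op_cost_pp = 0, exposure_prod_loss_pp = 0
  )
  lt <- test_lt()
  arms <- build_arms(p)
  a <- discounted_totals(run_cohort(p, arms$limited, lt))
  b <- discounted_totals(run_cohort(p, arms$year_round, lt))
  expect_lt(abs(a$cost - b$cost), 1e-12)
  expect_lt(abs(a$qalys - b$qalys), 1e-12)
})

test_that("raising the anxiety noise risk worsens the exposed arm monotonically", {
  p <- test_params()
  lt <- test_lt()
  costs <- qalys <- numeric(0)
  for (rr in c(1, 1.4, 1.79, 2.4, 3.06)) {
    pi <- set_parameters(p, rr_anx_noise = rr)
    tot <- discounted_totals(run_cohort(pi, build_arms(pi)$year_round, lt))
    costs <- c(costs, tot$cost)
    qalys <- c(qalys, tot$qalys)
  }
  expect_true(all(diff(costs) > 0))
  expect_true(all(diff(qalys) < 0))
})

test_that("once-only anxiety lowers anxiety burden relative to recurrent anxiety", {
  p <- test_params()
  lt <- test_lt()
  arm <- build_arms(p)$year_round
  recur <- discounted_totals(run_cohort(p, arm, lt))
  once <- discounted_totals(run_cohort(p, arm, lt, anxiety_once = TRUE))
  expect_lt(once$cost, recur$cost)
  expect_gt(once$qalys, recur$qalys)
})

test_that("half-cycle correction changes totals only modestly", {
  p <- test_params()
  lt <- test_lt()
  arm <- build_arms(p)$limited
  plain <- discounted_totals(run_cohort(p, arm, lt))
  hc <- discounted_totals(run_cohort(p, arm, lt, half_cycle = TRUE))
  expect_false(isTRUE(all.equal(plain$qalys, hc$qalys)))
  expect_lt(abs(plain$qalys - hc$qalys), 1)
  expect_lt(hc$qalys, plain$qalys) # dying fractions contribute half their cycle
})

test_that("a three-cycle toy cohort matches a hand-computed expectation", {
  # no events, no costs: pure survival-weighted discounted utility
  p <- test_params(
    cvd_risk = tibble::tibble(age_low = 18, age_high = Inf, mean = 1e-12, se = 1e-13),
    p_anxiety_base = 0, cvd_prevalence_init = 0,
    exposure_op_cost_pp = 0, exposure_prod_loss_pp = 0,
    discount_rate = 0.03
  )
  tr <- run_cohort(p, build_arms(p)$limited, toy_lt(q = c(0.1, 0.2, 1.0)))
  tot <- discounted_totals(tr)
  expect_equal(tot$cost, 0, tolerance = 1e-6)
  expect_equal(
    tot$qalys,
    1 + 0.9 / 1.03 + 0.9 * 0.8 / 1.03^2,
    tolerance = 1e-9
  )
})
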