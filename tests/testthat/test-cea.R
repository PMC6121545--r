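totals <- function(arm, cost, qalys) tibble::tibble(arm = arm, cost = cost, qalys = qalys)

test_that("ICER arithmetic and dominance classification cover all quadrants", {
  r <- icer(totals("a", 11288, 18.72), totals("b", 0, 17.59))
  expect_equal(r$icer, 11288 / 1.13, tolerance = 1e-9)
  expect_equal(r$dominance, "tradeoff")

  expect_equal(icer(totals("a", -5, 1), totals("b", 0, 0))$dominance, "dominant")
  expect_equal(icer(totals("a", 5, -1), totals("b", 0, 0))$dominance, "dominated")
  expect_equal(icer(totals("a", 5, 0), totals("b", 0, 0))$dominance, "dominated")
  expect_equal(icer(totals("a", -5, 0), totals("b", 0, 0))$dominance, "dominant")
  eq <- icer(totals("a", 0, 0), totals("b", 0, 0))
  expect_equal(eq$dominance, "equivalent")
  expect_true(is.na(eq$icer))
  # tidy/glance round out the broom interface
  expect_equal(nrow(tidy(r)), 3)
  expect_equal(glance(r)$dominance, "tradeoff")
})

test_that("ICER is invariant to a shared cost shift", {
  base <- icer(totals("a", 200, 2), totals("b", 100, 1))
  shifted <- icer(totals("a", 200 + 5000, 2), totals("b", 100 + 5000, 1))
  expect_equal(base$icer, shifted$icer)
  expect_equal(base$inc_cost, shifted$inc_cost)
})

test_that("PSA is seed-reproducible and a single draw runs", {
  p <- test_params()
  lt <- test_lt()
  a <- run_psa(p, lt, n_draws = 25, seed = 3)
  b <- run_psa(p, lt, n_draws = 25, seed = 3)
  expect_identical(a, b)
  one <- run_psa(p, lt, n_draws = 1, seed = 9)
  expect_equal(nrow(one), 1)
  expect_true(is.finite(one$inc_cost) && is.finite(one$inc_qaly))
})

test_that("CEAC equals brute-force net-monetary-benefit counting", {
  psa <- run_psa(test_params(), test_lt(), n_draws = 400, seed = 21)
  grid <- c(0, 25000, 50000, 100000, 200000)
  curve <- ceac(psa, grid)
  for (i in seq_along(grid)) {
    hand <- sum(grid[i] * psa$inc_qaly - psa$inc_cost > 0) / nrow(psa)
    expect_identical(curve$prob_cost_effective[i], hand)
  }
  # limiting identities
  expect_equal(curve$prob_cost_effective[1], mean(psa$inc_cost < 0))
  far <- ceac(psa, 1e12)$prob_cost_effective
  expect_equal(far, mean(psa$inc_qaly > 0))
  expect_error(ceac(psa, numeric(0)), "empty WTP")
  expect_error(ceac(psa[0, ], 0), "empty PSA")
})

test_that("psa_summary recounts its own sample", {
  psa <- run_psa(test_params(), test_lt(), n_draws = 300, seed = 8)
  s <- psa_summary(psa)
  expect_equal(s$p_cost_saving, mean(psa$inc_cost < 0 & psa$inc_qaly > 0))
  expect_equal(s$ceac_at_0, ceac(psa, 0)$prob_cost_effective)
  expect_equal(
    s$p_icer_below_threshold,
    mean(psa$inc_cost > 0 & psa$inc_qaly > 0 & psa$inc_cost / psa$inc_qaly < 1e5)
  )
  expect_equal(glance(psa)$ceac_at_50k, s$ceac_at_50k)
})

test_that("one-way analysis pins parameters and reports a sorted range", {
  p <- test_params()
  lt <- test_lt()
  base <- run_cea(p, lt)
  pin <- one_way(p, lt, "rr_anx_noise", 1.79, 1.79)
  expect_equal(pin$icer_min, base$icer, tolerance = 1e-12)
  expect_equal(pin$icer_max, base$icer, tolerance = 1e-12)
  row <- one_way(p, lt, "discount_rate", 0, 0.05)
  expect_lte(row$icer_min, row$icer_max)
  expect_error(one_way(p, lt, "rr_anx_noise", 2, 1), "low")
  expect_error(one_way(p, lt, "no_such", 1, 2), "unknown parameter")
})

test_that("tornado rows are ordered by descending ICER spread", {
  p <- test_params()
  lt <- test_lt()
  ranges <- default_owsa_ranges()[c(1, 5, 17), ] # anxiety RR, CVD RR, discount
  tor <- tornado_analysis(p, lt, ranges)
  expect_equal(nrow(tor), 3)
  expect_true(all(diff(tor$spread) <= 0))
  expect_equal(tor$parameter[1], "rr_anx_noise") # dominant driver
  expect_true(is.finite(attr(tor, "base_icer")))
})

test_that("stricter-threshold scenario reduces to the base case and scales linearly", {
  p <- test_params()
  lt <- test_lt()
  base <- run_cea(p, lt)
  same <- scenario_population(p, lt, population = p$population_60db)
  expect_equal(same$inc_cost, base$inc_cost, tolerance = 1e-12)
  expect_equal(same$icer, base$icer, tolerance = 1e-12)

  half <- scenario_population(p, lt, population = p$population_60db / 2)
  manual <- run_cea(
    set_parameters(p,
      exposure_op_cost_pp = 2 * p$exposure_op_cost_pp,
      exposure_prod_loss_pp = 2 * p$exposure_prod_loss_pp
    ),
    lt
  )
  expect_equal(half$inc_cost, manual$inc_cost, tolerance = 1e-12)
  expect_error(scenario_population(p, lt, population = 0), "> 0")
})
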