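test_that("annualization turns 5-day counts into yearly delayed flights", {
  scs <- default_delay_scenarios(hourly_wage_usd = 10)
  expect_equal(annual_delayed_flights(scs$limited), 14892)
  expect_equal(annual_delayed_flights(scs$year_round), 876)
  zero <- delay_scenario("limited", delay_min = 10, delayed_per_5day = 0)
  expect_equal(annual_delayed_flights(zero), 0)
  expect_equal(operating_cost_annual(zero), 0)
})

test_that("operating cost equation matches hand evaluation of the defaults", {
  scs <- default_delay_scenarios(hourly_wage_usd = 10)
  # (45.7/60 h)(900 km/h)(0.621371 mi/km)(0.116 $/seat-mi)(176 seats)(14,892/yr)
  expect_equal(operating_cost_annual(scs$limited), 129503685, tolerance = 1e-6)
  expect_equal(operating_cost_annual(scs$year_round), 4217329.4, tolerance = 1e-6)
  inc <- incremental_delay_costs(scs$limited, scs$year_round)
  expect_equal(
    inc$operating_cost[inc$arm == "incremental"], 125286356,
    tolerance = 1e-6
  )
})

test_that("cost equations are linear in every factor", {
  base <- delay_scenario("limited",
    delay_min = 30, delayed_per_5day = 100,
    hourly_wage_usd = 20
  )
  for (f in c("delay_min", "delayed_per_5day", "seats", "casm_usd_per_seat_mile", "speed_kmh")) {
    doubled <- base
    doubled[[f]] <- base[[f]] * 2
    expect_equal(operating_cost_annual(doubled), 2 * operating_cost_annual(base))
  }
  wage2 <- base
  wage2$hourly_wage_usd <- 40
  expect_equal(productivity_loss_annual(wage2), 2 * productivity_loss_annual(base))
})

test_that("incremental costs are antisymmetric under arm swap", {
  scs <- default_delay_scenarios(hourly_wage_usd = 10)
  ab <- incremental_delay_costs(scs$limited, scs$year_round)
  ba <- incremental_delay_costs(scs$year_round, scs$limited)
  expect_equal(
    ab$operating_cost[ab$arm == "incremental"],
    -ba$operating_cost[ba$arm == "incremental"]
  )
  expect_equal(
    ab$productivity_loss[ab$arm == "incremental"],
    -ba$productivity_loss[ba$arm == "incremental"]
  )
})

test_that("productivity equation requires a wage and scales from seat-hours", {
  sc <- delay_scenario("limited", delay_min = 45.7, delayed_per_5day = 204)
  expect_error(productivity_loss_annual(sc), "hourly_wage_usd")
  zero_wage <- delay_scenario("limited",
    delay_min = 45.7, delayed_per_5day = 204,
    hourly_wage_usd = 0
  )
  expect_equal(productivity_loss_annual(zero_wage), 0)
  # incremental delayed seat-hours: (45.7/60)*176*14892 - (25.3/60)*176*876
  scs <- default_delay_scenarios(hourly_wage_usd = 1)
  inc <- incremental_delay_costs(scs$limited, scs$year_round)
  expect_equal(
    inc$productivity_loss[inc$arm == "incremental"], 1931311.4,
    tolerance = 1e-6
  )
})

test_that("calibration recovers the factor/wage implied by a published total", {
  scs <- default_delay_scenarios(hourly_wage_usd = 10)
  k <- calibrate_km_to_mile(scs$limited, scs$year_round, 127040655)
  expect_equal(k, 0.63007, tolerance = 1e-4)
  recal <- default_delay_scenarios(hourly_wage_usd = 10, km_to_mile = k)
  inc <- incremental_delay_costs(recal$limited, recal$year_round)
  expect_equal(inc$operating_cost[inc$arm == "incremental"], 127040655, tolerance = 1e-6)

  w <- calibrate_wage(scs$limited, scs$year_round, 19956042)
  expect_equal(w, 10.3329, tolerance = 1e-4)
})

test_that("per-person conversion divides exactly and rejects empty populations", {
  expect_equal(round(per_person(127040655, 83807)), 1516)
  expect_equal(round(per_person(19956042, 83807)), 238)
  expect_equal(per_person(0, 83807), 0)
  expect_error(per_person(100, 0), "> 0")
})

test_that("income distribution arithmetic gives the mean wage", {
  eq <- income_distribution(rep(0.25, 4), c(10000, 30000, 70000, 150000))
  expect_equal(mean_hourly_wage(eq), 65000 / 2080)
  # wage of $10/h from a $20,800 mean income over 2080 hours
  expect_equal(
    sum(eq$share * eq$mean_income * 2) / 2080,
    2 * mean_hourly_wage(eq)
  )
  expect_error(income_distribution(c(0.5, 0.5, 0.2, 0.1), 1:4 * 1e4), "sum to 1")
  expect_error(income_distribution(rep(0.25, 4), c(2, 1, 3, 4) * 1e4), "increasing")
  expect_error(mean_hourly_wage(eq, hours_per_year = 0), "> 0")
  d <- default_income_distribution()
  expect_equal(sum(d$share), 1)
  expect_gt(mean_hourly_wage(d), 30)
})
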