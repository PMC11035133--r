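test_that("soil presets reproduce the two reference water holding capacities", {
  low <- soil_preset("low_swhc")
  high <- soil_preset("high_swhc")
  expect_equal(low$swhc, 62, tolerance = 1e-9)
  expect_equal(low$total_depth, 1010)
  expect_equal(high$swhc, 156, tolerance = 1e-9)
  expect_equal(high$total_depth, 1200)
  expect_true(all(low$ll < low$dul & low$dul < low$sat))
  expect_error(soil_profile(100, ll = 0.3, dul = 0.2, sat = 0.4), "LL < DUL")
})

test_that("fractional resets fill top-down to the requested available water", {
  p <- soil_preset("high_swhc")
  st0 <- reset_fractional_asw(p, 0)
  expect_equal(available_soil_water(st0), 0, tolerance = 1e-12)
  expect_equal(st0$sw, p$ll * p$layer_thickness)

  st1 <- reset_fractional_asw(p, 1)
  expect_equal(available_soil_water(st1), 156, tolerance = 1e-9)
  expect_equal(available_soil_water(reset_fractional_asw(soil_preset("low_swhc"), 1)),
               62, tolerance = 1e-9)

  st <- reset_fractional_asw(p, 0.2)
  expect_equal(available_soil_water(st), 31.2, tolerance = 1e-9)
  # top-down: surface layer saturated to DUL before any deeper layer is wetted
  cap <- (p$dul - p$ll) * p$layer_thickness
  fill <- st$sw - p$ll * p$layer_thickness
  expect_equal(fill[1], cap[1])
  expect_equal(sum(fill[3:7]), 31.2 - cap[1] - fill[2], tolerance = 1e-9)

  expect_error(reset_fractional_asw(p, 1.2), "fraction")
})

test_that("the daily step conserves mass and passes saturated rain through", {
  p <- soil_preset("low_swhc")
  st <- reset_fractional_asw(p, 0.5)

  # identity with zero fluxes
  st2 <- step_water_balance(st, 0, 0, 0)
  expect_equal(st2$sw, st$sw)

  # at DUL everywhere with full drainage, 10 mm passes straight through
  full <- new_state_at_dul <- reset_fractional_asw(p, 1)
  out <- step_water_balance(full, 10, 0, 0, drainage_coef = 1)
  expect_equal(out$sw, full$sw, tolerance = 1e-12)
  expect_equal(unname(out$cum["drainage"]), 10, tolerance = 1e-12)

  # random flux sequences close the balance to machine precision
  set.seed(99)
  st <- reset_fractional_asw(p, 0.4)
  storage0 <- sum(st$sw)
  for (d in 1:200) {
    rain <- stats::rexp(1, 1 / 5) * (stats::runif(1) < 0.4)
    evap <- stats::runif(1, 0, 3)
    sup <- water_supply(st, 800)
    uptake <- stats::runif(1, 0, sup)
    st <- step_water_balance(st, rain, evap, uptake, drainage_coef = 0.5)
    delta <- sum(st$sw) - storage0
    flux <- st$cum["rain_in"] - st$cum["drainage"] - st$cum["soil_evap"] -
      st$cum["transpiration"]
    expect_lt(abs(delta - unname(flux)), 1e-9)
    # layer bounds respected
    expect_true(all(st$sw >= p$ll * p$layer_thickness - 1e-9))
    expect_true(all(st$sw <= p$sat * p$layer_thickness + 1e-9))
  }

  expect_error(step_water_balance(st, -1, 0, 0), "non-negative")
  dry <- reset_fractional_asw(p, 0)
  expect_error(step_water_balance(dry, 0, 0, 5), "supply")
})

test_that("root water supply follows kl-weighted available water", {
  # single rooted layer, 10 mm above LL, kl 0.07 -> 0.7 mm/d
  p1 <- soil_profile(200, ll = 0.1, dul = 0.2, sat = 0.3, kl = 0.07)
  st <- reset_fractional_asw(p1, 0.5)  # 10 mm of 20 mm capacity
  expect_equal(water_supply(st, 200), 0.7, tolerance = 1e-12)
  # partial root penetration scales linearly
  expect_equal(water_supply(st, 100), 0.35, tolerance = 1e-12)
  expect_equal(water_supply(st, 0), 0)

  # all layers at LL -> zero supply
  p <- soil_preset("low_swhc")
  expect_equal(water_supply(reset_fractional_asw(p, 0), 1010), 0)

  # doubling root depth with uniform moisture doubles supply (inside profile)
  pu <- soil_profile(rep(100, 8), ll = 0.1, dul = 0.2, sat = 0.3, kl = 0.07)
  stu <- new_soil_state_uniform <- reset_fractional_asw(pu, 1)
  expect_equal(water_supply(stu, 400), 2 * water_supply(stu, 200),
               tolerance = 1e-12)

  # monotone in stored water, bounded by available water in the root zone
  st_half <- reset_fractional_asw(pu, 0.5)
  expect_lt(water_supply(st_half, 800), water_supply(stu, 800))
  expect_lte(water_supply(stu, 800), available_soil_water(stu))
})
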