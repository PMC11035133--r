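test_that("cultivar presets carry the published coefficient values", {
  e <- cultivar("CSM63E")
  l <- cultivar("CSM335")
  expect_equal(c(e$ppcrit1, e$ppcrit2), c(11.5, 13.5))
  expect_equal(c(e$ppslope, l$ppslope), c(126, 226))
  expect_equal(c(e$tt_flower_to_maturity, l$tt_flower_to_maturity), c(484, 518))
  expect_equal(c(e$tt_endjuv_to_init_base, l$tt_endjuv_to_init_base), c(50, 50))
  expect_equal(c(e$tt_flag_to_flower, e$tt_flower_to_start_grain,
                 e$tt_maturity_to_ripe), c(170, 80, 1))
  expect_equal(c(e$dm_per_seed, l$dm_per_seed), c(0.00083, 0.0015))
  expect_equal(c(e$max_gf_rate, l$max_gf_rate), c(0.090, 0.045))
  expect_equal(c(e$amax_slope, l$amax_slope), c(17.163, 32.9))
  expect_equal(c(e$amax_intercept, l$amax_intercept), c(-71.354, -296))
  expect_equal(c(e$largest_leaf_multiplier, l$largest_leaf_multiplier),
               c(0.783, 0.698))

  # YAML round-trip preserves every coefficient
  f <- tempfile(fileext = ".yml")
  write_cultivar(l, f)
  expect_equal(read_cultivar(f), l)
  unlink(f)

  expect_error(cultivar("CSM63E", ppcrit1 = 14), "Ppcrit1")
})

test_that("daily thermal time follows the broken-linear temperature response", {
  cv <- cultivar("CSM63E")
  expect_equal(daily_thermal_time(11, 11, cv), 0)
  expect_equal(daily_thermal_time(30, 22, cv), 15)      # mean 26 - base 11
  expect_equal(daily_thermal_time(30, 30, cv), 19)      # optimum
  expect_equal(daily_thermal_time(42, 42, cv), 0)       # ceiling
  expect_equal(daily_thermal_time(40, 32, cv), 19 / 2)  # mean 36, halfway down
  expect_error(daily_thermal_time(10, 20, cv), "tmax")
})

test_that("the photoperiod response is broken-linear with a plateau", {
  e <- cultivar("CSM63E"); l <- cultivar("CSM335")
  expect_equal(endjuv_to_init_duration(11.0, e), 50)
  expect_equal(endjuv_to_init_duration(11.0, l), 50)
  expect_equal(endjuv_to_init_duration(13.5, e), 50 + 126 * 2)
  expect_equal(endjuv_to_init_duration(12.5, l), 50 + 226 * 1)
  # flat above Ppcrit2 and below Ppcrit1
  expect_equal(endjuv_to_init_duration(14.5, e), endjuv_to_init_duration(13.5, e))
  expect_equal(endjuv_to_init_duration(10.2, l), endjuv_to_init_duration(11.5, l))
  # monotone non-decreasing over the whole domain
  pp <- seq(9, 16, by = 0.1)
  expect_true(all(diff(endjuv_to_init_duration(pp, l)) >= 0))
})

test_that("total leaf number is the plastochron count rounded half-up", {
  cv34 <- cultivar("CSM63E", plastochron = 34)
  expect_equal(total_leaf_number(0, cv34), 4L)
  expect_equal(total_leaf_number(408, cv34), 16L)   # 4 + 12
  expect_equal(total_leaf_number(425, cv34), 17L)   # 4 + 12.5, ties up
  tt <- seq(0, 900, by = 10)
  expect_true(all(diff(total_leaf_number(tt, cv34)) >= 0))
})

test_that("the sowing rule matches a brute-force scan of the window", {
  p <- soil_preset("high_swhc")

  # zero-rain season, dry soil: forced on the last window day
  dry <- constant_weather(rain = 0)
  res <- sowing_date(dry, reset_fractional_asw(p, 0))
  expect_equal(res$doy, 196)
  expect_true(res$forced)

  # daily 3 mm from June 1: 7-day sum reaches 21 on June 7 (doy 158)
  rain <- numeric(365); rain[152:365] <- 3
  w <- constant_weather(rain = rain)
  res <- sowing_date(w, reset_fractional_asw(p, 1))
  expect_equal(res$doy, 158)
  expect_false(res$forced)

  # 25 mm spread over June 3-7 with wet soil: brute-force oracle over all
  # window days picks the first day whose trailing sum qualifies
  rain <- numeric(365); rain[154:158] <- 5
  w <- constant_weather(rain = rain)
  oracle <- NA
  for (d in 152:196) {
    if (sum(rain[max(1, d - 6):d]) >= 20) { oracle <- d; break }
  }
  res <- sowing_date(w, reset_fractional_asw(p, 1))
  expect_equal(res$doy, oracle)

  expect_error(sowing_date(constant_weather(ndays = 150),
                           reset_fractional_asw(p, 1)), "window")
})

test_that("the stage machine hits its thermal targets exactly, in order", {
  cv <- cultivar("CSM63E")
  # constant 15 degCd/day (tmax 30 / tmin 22), fixed short photoperiod
  w <- constant_weather(tmax = 30, tmin = 22, photoperiod = 11.0)
  run <- grow_season(w, cv, soil_preset("high_swhc"),
                     control = sim_control(water_limited = FALSE),
                     sowing_doy = 152)
  s <- run$summary
  expect_equal(s$flower_to_maturity_tt, 484)
  # at 15 degCd/day the calendar gap is ceiling(484/15) give or take the
  # sub-daily position of the flowering transition
  expect_true((s$maturity_doy - s$flowering_doy) %in% c(32L, 33L))

  # short days: no photoperiod extension, so flowering target is the sum of
  # the fixed phase durations plus the leaf-driven flag-leaf phase
  tr <- run$phenology$transition_tt
  expect_equal(unname(tr["end_juvenile"]), 200)
  expect_equal(unname(tr["panicle_initiation"]), 250)  # base 50 at 11 h
  expect_equal(unname(tr["flowering"] - tr["flag_leaf"]), 170)
  expect_equal(unname(run$phenology$targets["start_grain_fill"] - tr["flowering"]), 80)

  # stages appear in canonical order with non-decreasing transition times
  stage_order <- c("presowing", "sowing", "emergence", "end_juvenile",
                   "panicle_initiation", "flag_leaf", "flowering",
                   "start_grain_fill", "maturity", "ripe")
  idx <- match(names(tr), stage_order)
  expect_true(all(diff(idx) == 1))
  expect_true(all(diff(unname(tr)) >= 0))

  # a photoperiod-insensitive control is unaffected by day length
  cv0 <- cultivar("CSM335", ppslope = 0)
  f_short <- grow_season(constant_weather(photoperiod = 11), cv0,
                         soil_preset("high_swhc"),
                         control = sim_control(water_limited = FALSE),
                         sowing_doy = 152)$summary$flowering_tt
  f_long <- grow_season(constant_weather(photoperiod = 13.4), cv0,
                        soil_preset("high_swhc"),
                        control = sim_control(water_limited = FALSE),
                        sowing_doy = 152)$summary$flowering_tt
  expect_equal(f_short, f_long)

  # under identical long days the photoperiod-sensitive cultivar flowers later
  w <- wet_weather()
  fe <- grow_season(w, cultivar("CSM63E"), soil_preset("high_swhc"),
                    sowing_doy = 160)$summary$flowering_doy
  fl <- grow_season(w, cultivar("CSM335"), soil_preset("high_swhc"),
                    sowing_doy = 160)$summary$flowering_doy
  expect_gt(fl, fe)
})

test_that("photoperiod-slope calibration recovers generating slopes", {
  # noiseless data on the linear segment: exact recovery
  pp <- seq(11.7, 13.3, length.out = 10)
  obs <- data.frame(photoperiod = pp, tt = 50 + 226 * (pp - 11.5))
  fit <- fit_ppslope(obs)
  expect_equal(fit$slope, 226, tolerance = 1e-9)
  expect_equal(fit$base, 50, tolerance = 1e-9)

  # noisy recovery within 5% at a fixed seed
  set.seed(1905)
  pp <- stats::runif(20, 11.6, 13.4)
  obs <- data.frame(photoperiod = pp,
                    tt = 50 + 126 * (pp - 11.5) + stats::rnorm(20, 0, 10))
  expect_lt(abs(fit_ppslope(obs)$slope - 126) / 126, 0.05)

  # degenerate designs are rejected
  expect_error(fit_ppslope(data.frame(photoperiod = c(12, 12), tt = c(100, 150))),
               "unidentifiable")
  expect_error(fit_ppslope(data.frame(photoperiod = c(10, 14), tt = c(50, 500))),
               "unidentifiable")
})
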