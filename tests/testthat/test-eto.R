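test_that("vapour-pressure auxiliaries match direct arithmetic", {
  expect_equal(saturation_vapor_pressure(0), 0.6108)
  expect_equal(saturation_vapor_pressure(20),
               0.6108 * exp(17.27 * 20 / (20 + 237.3)))
  t <- seq(-10, 45, by = 0.5)
  expect_true(all(diff(saturation_vapor_pressure(t)) > 0))

  expect_equal(slope_svp(0), 4098 * 0.6108 / 237.3^2)
  expect_true(all(slope_svp(t) > 0))
  # numeric-derivative oracle; the convention rounds 17.27 * 237.3 to the
  # constant 4098, which puts the formula ~4e-5 relative from the true
  # derivative of the saturation curve
  h <- 1e-4
  fd <- (saturation_vapor_pressure(25 + h) -
           saturation_vapor_pressure(25 - h)) / (2 * h)
  expect_lt(abs(slope_svp(25) - fd), 1e-5)
  exact_const <- 17.27 * 237.3
  expect_lt(abs(slope_svp(25) * exact_const / 4098 - fd), 1e-9)

  expect_equal(psychrometric_constant(0), 0)
  expect_equal(psychrometric_constant(101.3), 0.0673645)
  expect_equal(psychrometric_constant(50), psychrometric_constant(100) / 2)
})

test_that("Penman-Monteith reduces correctly in limiting cases", {
  d <- slope_svp(25)
  g <- psychrometric_constant()
  es <- saturation_vapor_pressure(25)
  # both numerator terms vanish
  expect_equal(eto_penman_monteith(d, g, rn = 12, g = 12, t = 25, u2 = 2,
                                   es = es, ea = es), 0)
  # no wind, saturated air: radiation term only
  expect_equal(eto_penman_monteith(d, g, rn = 14, g = 0.5, t = 25, u2 = 0,
                                   es = es, ea = es),
               0.408 * d * (14 - 0.5) / (d + g))
  # negative value preserved unless clamped
  neg <- eto_penman_monteith(d, g, rn = 0, g = 2, t = 25, u2 = 0,
                             es = es, ea = es)
  expect_lt(neg, 0)
  expect_equal(eto_penman_monteith(d, g, rn = 0, g = 2, t = 25, u2 = 0,
                                   es = es, ea = es, clamp_negative = TRUE), 0)
  expect_error(eto_penman_monteith(d, g, 12, 0, 25, 2, es = 1, ea = 2),
               "es >= ea")
})

test_that("a full mid-summer day matches a term-by-term evaluation", {
  t <- 24; u2 <- 2.3; rn <- 15.2; gflux <- 0.4; rh <- 55; p <- 96.5
  es <- 0.6108 * exp(17.27 * t / (t + 237.3))
  ea <- rh / 100 * es
  delta <- 4098 * es / (t + 237.3)^2
  gamma <- 0.000665 * p
  # independent stepwise evaluation
  rad_term <- 0.408 * delta * (rn - gflux)
  aero_term <- gamma * (900 / (t + 273)) * u2 * (es - ea)
  denom <- delta + gamma * (1 + 0.34 * u2)
  expect_equal(
    eto_penman_monteith(delta, gamma, rn, gflux, t, u2, es, ea),
    (rad_term + aero_term) / denom
  )
  # increasing in the vapour pressure deficit, all else fixed
  vpd <- seq(0, 2, by = 0.1)
  vals <- eto_penman_monteith(delta, gamma, rn, gflux, t, u2,
                              es = es, ea = pmax(es - vpd, 0))
  expect_true(all(diff(vals) > 0))
})

test_that("weather-table ETo derives missing humidity terms the FAO-56 way", {
  w <- make_weather(5, tmean = 24, rh_mean = 55, u2 = 2.3, rn = 15.2, g = 0.4)
  out <- eto_from_weather(w, pressure = 96.5)
  es <- (saturation_vapor_pressure(29) + saturation_vapor_pressure(19)) / 2
  manual <- eto_penman_monteith(slope_svp(24), psychrometric_constant(96.5),
                                15.2, 0.4, 24, 2.3, es, 0.55 * es)
  expect_equal(out$eto_mm, rep(manual, 5))
  expect_named(out, c("date", "eto_mm"))
})

test_that("irrigation triggers at the accumulation threshold and doses by fraction", {
  # eight days of exactly 1 mm: one event of 8 mm at day 8
  dates <- as.Date("2014-02-01") + 0:7
  full <- schedule_irrigation(rep(1, 8), fraction = 1, trigger = 8,
                              dates = dates)
  expect_equal(nrow(full), 1L)
  expect_equal(full$applied_depth_lm2, 8)
  deficit <- schedule_irrigation(rep(1, 8), fraction = 0.4, trigger = 8,
                                 dates = dates)
  expect_equal(deficit$applied_depth_lm2, 3.2)
  expect_equal(nrow(schedule_irrigation(rep(0, 30), fraction = 1)), 0L)
  expect_equal(season_water_total(schedule_irrigation(rep(0, 30), 1)), 0)
  expect_error(schedule_irrigation(rep(1, 8), fraction = 0), "fraction")
  expect_error(schedule_irrigation(rep(1, 8), fraction = 1.2), "fraction")
})

test_that("every event sits in the trigger band and totals scale with fraction", {
  set.seed(5)
  eto <- pmax(0, rnorm(120, mean = 3, sd = 2))
  ev <- schedule_irrigation(eto, fraction = 1, trigger = 8)
  expect_true(all(ev$accumulated_eto_mm >= 8))
  # accumulation minus the triggering day's contribution was below trigger
  last_day <- eto[match(ev$date, seq_along(eto))]
  expect_true(all(ev$accumulated_eto_mm - last_day < 8))
  # proportionality across fractions on the same series
  tot1 <- season_water_total(ev)
  tot04 <- season_water_total(schedule_irrigation(eto, 0.4, trigger = 8))
  expect_equal(tot04, 0.4 * tot1)
  expect_equal(season_water_total(data.frame(applied_depth_lm2 = c(8, 6))), 14)
})
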