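test_that("forcing evaluates to its defining formula", {
  f <- temperature_forcing(mean = 1, amplitude = 2, period = 1, phase = 0.25,
                           warming_rate = 0.1, warming_duration = 10)
  t <- c(0, 0.5, 2, 20)
  expect_equal(forcing_values(f, t),
               1 + 2 * sin(2 * pi * (t - 0.25)) + 0.1 * pmin(t, 10))
  expect_error(temperature_forcing(amplitude = -1))
})

test_that("zero forcing leaves the geotherm untouched", {
  f <- temperature_forcing(mean = 1.25, amplitude = 0)
  fld <- propagate_temperature(f, sediment_column(60, 0.25), duration = 5)
  T0 <- 1.25 + 0.044 * fld$column$cell_centres
  expect_lt(max(abs(sweep(fld$T, 2, T0))), 1e-9)
})

test_that("the annual wave decays and lags as the damped-wave solution", {
  fld <- propagate_temperature(temperature_forcing(), duration = 12,
                               snap_every = 1)
  zc <- fld$column$cell_centres
  last <- fld$times > max(fld$times) - 1
  tt <- fld$times[last]
  # harmonic regression per depth removes snapshot-sampling bias
  X <- cbind(1, sin(2 * pi * tt), cos(2 * pi * tt))
  cf <- qr.solve(X, fld$T[last, ])
  amp <- sqrt(cf[2, ]^2 + cf[3, ]^2)
  phs <- atan2(-cf[3, ], cf[2, ])
  d <- sqrt(2 * 33.4273 / (2 * pi))
  expect_equal(d, 3.26, tolerance = 0.001)
  sel <- zc > 0.1 & zc < 10
  pred <- 3.25 * exp(-zc[sel] / d)
  expect_lt(max(abs(amp[sel] - pred) / pred), 0.02)
  # phase lag z/d radians within 5% (unwrapped, relative to the top cell)
  lag <- (phs[sel] - phs[1]) %% (2 * pi)
  pred_lag <- (zc[sel] - zc[1]) / d
  expect_lt(max(abs(lag - pred_lag) / pmax(pred_lag, 0.3)), 0.05)
})

test_that("temperatures stay within the forcing and geotherm bounds", {
  # phase 0 starts the boundary at the initial-condition mean, so the run is
  # free of the startup transient and the bound is tight
  f <- temperature_forcing(phase = 0, warming_rate = 0.05,
                           warming_duration = 20)
  fld <- propagate_temperature(f, sediment_column(60, 0.1), duration = 25)
  lo <- min(forcing_values(f, seq(0, 25, by = 0.01)), 1.25)
  hi <- max(forcing_values(f, seq(0, 25, by = 0.01)),
            1.25 + 0.044 * 60)
  rng <- hi - lo
  expect_lte(max(fld$T), hi + 0.01 * rng)
  expect_gte(min(fld$T), lo - 0.01 * rng)
})

test_that("the long-time mean converges to forcing mean plus the geotherm", {
  fld <- propagate_temperature(temperature_forcing(), sediment_column(60, 0.1),
                               duration = 11, snap_every = 1)
  last <- fld$times > 10
  mn <- colMeans(fld$T[last, ])
  pred <- 1.25 + 0.044 * fld$column$cell_centres
  expect_lt(max(abs(mn - pred) / pred), 0.01)
})

test_that("stability assessment flags exactly the cells above the boundary", {
  pb <- phase_boundary_profile()
  fld <- propagate_temperature(temperature_forcing(), duration = 6,
                               snap_every = 2)
  rep <- assess_stability(fld, pb)
  # brute-force scan oracle, cell by cell
  Teq <- pb$T_eq(fld$column$cell_centres)
  oracle <- sweep(fld$T, 2, Teq, `>`)
  expect_identical(rep$unstable, oracle)
  # a forcing that never reaches the boundary destabilizes nothing
  cold <- propagate_temperature(temperature_forcing(mean = 0, amplitude = 0.5),
                                sediment_column(60, 0.25), duration = 4)
  rep0 <- assess_stability(cold, pb)
  expect_identical(rep0$max_destabilization_depth, 0)
  expect_true(all(is.na(rep0$max_depth_t)))
})

test_that("warming scenarios apply the documented ramps", {
  # fast: 0.033 degC/yr for 30 yr is about one degree in total
  f_fast <- temperature_forcing(warming_rate = 0.033, warming_duration = 30)
  expect_equal(forcing_values(f_fast, 30) - forcing_values(f_fast, 0),
               0.99, tolerance = 1e-12)
  # slow: 0.005 degC/yr for 300 yr is 1.5 degrees
  f_slow <- temperature_forcing(warming_rate = 0.005, warming_duration = 300)
  expect_equal(forcing_values(f_slow, 300) - forcing_values(f_slow, 0), 1.5,
               tolerance = 1e-12)
  # warming_rate 0 reduces the scenario machinery to the seasonal run
  r_seas <- run_warming_scenario("seasonal", duration = 4)
  f0 <- temperature_forcing(); f0$warming_rate <- 0
  fld <- propagate_temperature(f0, duration = 4)
  expect_equal(r_seas$field$T, fld$T, tolerance = 1e-12)
})

test_that("the destabilized set grows monotonically under monotone warming", {
  r <- run_warming_scenario("slow", duration = 300, snap_every = 5)
  # compare annual-maximum destabilized depth across years: never shrinks
  # by more than the seasonal band
  yr <- floor(r$times)
  mx <- tapply(ifelse(is.na(r$max_depth_t), 0, r$max_depth_t), yr, max)
  expect_true(all(diff(mx) > -1e-9))
  expect_false(is.na(r$time_to_full_column_destabilization))
})
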