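test_that("dual-Monod AOM rate matches its closed form", {
  expect_equal(aom_rate(0.5, 5), 2 * 0.5 * 0.5)
  expect_identical(aom_rate(3, 0), 0)
  expect_identical(aom_rate(0, 3), 0)
  expect_equal(aom_rate(1e6, 1e6), 2, tolerance = 1e-3)
  expect_error(aom_rate(-1, 2), "non-negative")
  expect_error(aom_kinetics(k_max = 0), "positive")
})

test_that("spin-up reaches a genuine steady state", {
  cfg <- reduced_model_config()
  # no methane: the steady sulfate column is uniform at the top value
  cfg0 <- reduced_model_config(ch4_bottom_weak = 0)
  st0 <- spin_up_initial_state(cfg0, 1.5, settle_years = 0)
  expect_equal(st0$so4, rep(28, st0$column$n_cells), tolerance = 1e-6)
  expect_true(all(st0$ch4 < 1e-8))
  # with the default weak supply: one further century of stepping moves the
  # profile by less than 1e-8 relative
  st <- spin_up_initial_state(cfg, 1.5, verify = TRUE)
  expect_lt(st$drift, 1e-8)
  expect_equal(st$ch4_bottom, cfg$ch4_bottom_weak)
})

test_that("steady SMTZ depth agrees with an independent stiff-ODE solve", {
  skip_if_not_installed("deSolve")
  # Shooting across the reaction front is exponentially ill-conditioned in
  # either direction, so the independent oracle integrates an independently
  # written method-of-lines discretization (coarser grid, interleaved
  # banded Jacobian, smooth rate law, stiff time integrator) to steady
  # state.
  cfg <- reduced_model_config()
  th <- 1.5
  st <- spin_up_initial_state(cfg, th, settle_years = 0)
  smtz_pkg <- smtz_depth(st$column$cell_centres, st$so4)
  Ds <- list(so4 = porous_media_diffusivity(free_solution_diffusivity("sulfate", 0.56), th),
             ch4 = porous_media_diffusivity(free_solution_diffusivity("methane", 0.56), th))
  dz <- 0.1; n <- 600
  zc <- (seq_len(n) - 0.5) * dz
  iS <- seq(1, 2 * n, by = 2); iM <- seq(2, 2 * n, by = 2)
  rhs <- function(t, y, p) {
    s <- y[iS]; m <- y[iM]
    R <- 2 * s / (0.5 + s) * m / (5 + m)
    lap <- function(x, top, bottom) {
      xm <- c(if (is.null(top)) x[1] else 2 * top - x[1], x[-n])
      xp <- c(x[-1], if (is.null(bottom)) x[n] else 2 * bottom - x[n])
      (xm - 2 * x + xp) / dz^2
    }
    dy <- numeric(2 * n)
    dy[iS] <- Ds$so4 * lap(s, 28, NULL) - R
    dy[iM] <- Ds$ch4 * lap(m, 0, cfg$ch4_bottom_weak) - R
    list(dy)
  }
  y0 <- numeric(2 * n)
  y0[iS] <- pmax(28 * (1 - zc / 30), 0)
  y0[iM] <- pmin(zc / 60, 1) * cfg$ch4_bottom_weak
  out <- deSolve::lsoda(y0, c(0, 5e5, 1e6), rhs, parms = NULL,
                        rtol = 1e-7, atol = 1e-8,
                        jactype = "bandint", bandup = 2, banddown = 2,
                        maxsteps = 50000)
  expect_identical(nrow(out), 3L)   # integrator reached the final time
  final <- out[3, -1]
  # stationary: the last doubling of time barely moves the solution
  expect_lt(max(abs(final - out[2, -1])), 1e-3)
  smtz_oracle <- smtz_depth(zc, final[iS])
  expect_lt(abs(smtz_pkg - smtz_oracle), dz)
})

test_that("pulse simulation drives the sulfate front monotonically upward", {
  cfg <- reduced_model_config(gas_front_depth = 2.0)
  init <- spin_up_initial_state(cfg, 1.5, settle_years = 20)
  # duration 0 returns the initial state
  tr0 <- simulate_pulse(init, 0)
  expect_identical(tr0$so4[1, ], init$so4)
  # SMTZ depth non-increasing in time after the pulse
  tr <- simulate_pulse(init, 30, snapshot_times = seq(5, 30, by = 5))
  expect_true(all(diff(tr$smtz) <= 1e-9))
  # slower porous diffusion transports strictly less: with the reaction
  # switched (effectively) off, the methane invasion front at theta 2.2
  # lags the theta 1.5 front from identical initial fields and boundaries
  cfg0 <- reduced_model_config(gas_front_depth = 2.0,
                               kinetics = aom_kinetics(k_max = 1e-12))
  i15 <- spin_up_initial_state(cfg0, 1.5, settle_years = 0)
  i22 <- i15; i22$theta <- 2.2
  t15 <- simulate_pulse(i15, 20)
  t22 <- simulate_pulse(i22, 20)
  above <- i15$column$cell_centres < 2.0
  expect_true(all(t22$final$ch4[above] <= t15$final$ch4[above] + 1e-12))
  expect_gt(max(t15$final$ch4[above] - t22$final$ch4[above]), 0.5)
})

test_that("AOM consumes sulfate and methane 1:1 and controls the overlap zone", {
  cfg <- reduced_model_config(gas_front_depth = 2.0)
  init <- spin_up_initial_state(cfg, 1.5, settle_years = 0)
  # inventory bookkeeping: the drop of total sulfate not explained by the
  # boundary can only come from AOM, and the same moles of methane vanish
  tr <- simulate_pulse(init, 10)
  expect_gt(tr$cum_aom, 0)
  # overlap-zone width shrinks as k_max grows
  widths <- vapply(c(0.2, 2, 20), function(km) {
    cfgk <- reduced_model_config(gas_front_depth = 2.0,
                                 kinetics = aom_kinetics(k_max = km))
    ik <- spin_up_initial_state(cfgk, 1.5, settle_years = 0)
    trk <- simulate_pulse(ik, 15)
    zc <- ik$column$cell_centres
    sum(trk$final$so4 > 0.4 & trk$final$ch4 > 0.4) * cfgk$dx
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("saturation depth interpolates the solubility crossing", {
  expect_identical(saturation_depth(1:10, rep(10, 10), 64), Inf)
  expect_equal(saturation_depth(seq(0, 60, length.out = 601),
                                seq(0, 128, length.out = 601), 64), 30)
  expect_error(saturation_depth(1:5, 1:5, -1), "positive")
  # scan oracle on a pulse output
  cfg <- reduced_model_config(gas_front_depth = 2.0)
  init <- spin_up_initial_state(cfg, 1.5, settle_years = 0)
  tr <- simulate_pulse(init, 10)
  zc <- init$column$cell_centres
  sd_pkg <- saturation_depth(zc, tr$final$ch4, 32)
  idx <- which(tr$final$ch4 >= 32)[1]
  expect_lt(abs(sd_pkg - zc[idx]), cfg$dx)
})

test_that("onset fitting recovers an exact forward-model input", {
  ds <- generate_porewater_dataset(synthetic_profile_spec(seed = 3, noise_sd = 0))
  fit <- fit_onset(ds$profile, reduced_model_config(), thetas = 2.2,
                   hydrate_depth = ds$truth$hydrate_depth,
                   scan_resolution = 0.25)
  expect_equal(unname(fit$onset_years_by_tortuosity["2.2"]), ds$truth$onset,
               tolerance = 0.25 / ds$truth$onset)
  expect_true(fit$onset_interval[1] <= fit$onset_interval[2])
})

test_that("onset-fit methods expose the fit coherently", {
  ds <- generate_porewater_dataset(synthetic_profile_spec(seed = 11,
                                                          noise_sd = 0.02 * 28))
  fit <- fit_onset(ds$profile, reduced_model_config(), thetas = c(1.5, 2.2),
                   hydrate_depth = ds$truth$hydrate_depth, site_id = "synthetic")
  co <- coef(fit)
  expect_named(co, c("1.5", "2.2", "onset_min", "onset_max"))
  expect_equal(unname(co["onset_min"]), min(co[1:2]))
  expect_output(print(fit), "onset interval")
  expect_output(summary(fit), "kink at")
  pr <- predict(fit)
  expect_equal(nrow(pr), nrow(fit$observed))
  expect_true(all(is.finite(pr$so4)))
  res <- residuals(fit)
  expect_true(length(res) >= 8 && all(is.finite(res)))
  sims <- simulate(fit, nsim = 2, seed = 99)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$concentration, sims[[2]]$concentration))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("profiles without a kink are rejected with a shape error", {
  z <- seq(0.05, 3, by = 0.1)
  expect_error(fit_onset(data.frame(depth_mbsf = z, concentration = 28 - 0.5 * z)),
               "shape error")
  expect_error(detect_kink(z[1:5], rep(1, 5)), "at least 6")
})
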