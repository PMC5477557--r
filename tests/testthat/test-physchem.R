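test_that("free-solution diffusivities reproduce the bottom-water anchor values", {
  expect_equal(free_solution_diffusivity("sulfate", 0.56), 0.0158, tolerance = 5e-4)
  expect_equal(free_solution_diffusivity("methane", 0.56), 0.0301, tolerance = 5e-4)
  # positive temperature coefficient, linear in T
  expect_gt(free_solution_diffusivity("sulfate", 10),
            free_solution_diffusivity("sulfate", 0.56))
  for (sp in c("sulfate", "methane", "calcium", "ammonium")) {
    d <- free_solution_diffusivity(sp, c(0, 10, 20))
    expect_equal(d[2] - d[1], d[3] - d[2], tolerance = 1e-12)
    expect_true(all(d > 0))
  }
  expect_error(free_solution_diffusivity("xenon", 5))
  expect_error(free_solution_diffusivity("sulfate", 45), "temperature")
})

test_that("porous-medium corrections follow D/theta^2 and D/F", {
  expect_identical(porous_media_diffusivity(0.0301, 1), 0.0301)
  expect_equal(porous_media_diffusivity(0.0158, 1.5), 0.0158 / 2.25)
  expect_equal(porous_media_diffusivity(0.0158, 2.2), 0.0158 / 4.84)
  # monotone decreasing in tortuosity
  th <- c(1, 1.3, 1.7, 2.2, 3)
  expect_true(all(diff(porous_media_diffusivity(0.02, th)) < 0))
  expect_error(porous_media_diffusivity(0.02, 0.9), "tortuosity")
  expect_equal(formation_factor_diffusivity(0.03, 1.5), 0.02)
})

test_that("hydrate phase boundary matches the base-of-GHSZ anchor", {
  P60 <- hydrostatic_pressure(60, 380)
  expect_equal(hydrate_equilibrium_temperature(P60, 35), 4.05, tolerance = 0.3 / 4.05)
  # strictly increasing in pressure
  Teq <- hydrate_equilibrium_temperature(c(3, 4, 5))
  expect_true(all(diff(Teq) > 0))
  # salinity depression
  expect_lt(hydrate_equilibrium_temperature(4.5, 35),
            hydrate_equilibrium_temperature(4.5, 0))
  expect_error(hydrate_equilibrium_temperature(0.5), "correlation validity")
  # equilibrium pressure is the inverse mapping
  expect_equal(hydrate_equilibrium_pressure(
    hydrate_equilibrium_temperature(4.0, 35), 35), 4.0, tolerance = 1e-8)
})

test_that("methane solubility at hydrate equilibrium is near the 64 mM anchor", {
  s <- methane_solubility(1.25, 3.85, 35)
  expect_equal(s, 64, tolerance = 0.10)
  expect_identical(methane_solubility(1.25, 3.85, mode = "paper_constant"), 64)
  # warmer water in the stability field holds more methane at equilibrium
  expect_gt(methane_solubility(2.25, 3.85), methane_solubility(1.25, 3.85))
  expect_error(methane_solubility(1.25, 0.5), "correlation validity")
  # cross-check: at (T_eq(P), P) solubility is finite and positive
  P <- 4.5
  s2 <- methane_solubility(hydrate_equilibrium_temperature(P), P)
  expect_true(is.finite(s2) && s2 > 0)
})

test_that("phase_boundary_profile honours its anchor exactly", {
  pb <- phase_boundary_profile()
  expect_identical(pb$T_eq(60), 4.05)
  expect_equal(pb$T_eq(0), 4.05 - 60 * pb$slope)
  pb0 <- phase_boundary_profile(slope = 0)
  expect_identical(pb0$T_eq(c(0, 30, 60)), rep(4.05, 3))
  # default slope equals the finite difference of the correlation
  T0 <- hydrate_equilibrium_temperature(hydrostatic_pressure(0, 380))
  T1 <- hydrate_equilibrium_temperature(hydrostatic_pressure(60, 380))
  expect_equal(pb$slope, (T1 - T0) / 60)
  expect_error(phase_boundary_profile(column_depth = -1))
})

test_that("geothermal gradient and bulk heat diffusivity match their anchors", {
  expect_equal(geothermal_gradient(1.44, 4.05, 60), 0.0435)
  expect_equal(round(geothermal_gradient(1.44, 4.05, 60), 3), 0.044)
  expect_identical(geothermal_gradient(1.44, 1.44, 60), 0)
  expect_equal(geothermal_gradient(0, 6, 100), 0.06)
  expect_error(geothermal_gradient(1, 2, 0), "geometry")

  expect_identical(bulk_heat_diffusivity(), 33.4273)
  # single-phase limits of the computed mixing law
  kw <- bulk_heat_diffusivity(thermal_properties(porosity = 1), mode = "computed")
  ks <- bulk_heat_diffusivity(thermal_properties(porosity = 0), mode = "computed")
  expect_equal(kw, 0.56 / (1.03e6 * 4.2) * 3.1536e7, tolerance = 1e-10)
  expect_equal(kw, 4.08, tolerance = 0.01)
  expect_equal(ks, 8.05 / (2.60e6 * 0.73) * 3.1536e7, tolerance = 1e-10)
  expect_equal(ks, 133.8, tolerance = 0.01)
  expect_error(thermal_properties(lambda_w = -1))
})
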