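# closed-box elemental totals (mol per m2): solutes weighted by porosity,
# solids taken as bulk
elemental_totals <- function(state) {
  phi <- state$column$porosity; dx <- state$column$dx
  s <- state$solutes; so <- state$solids
  c(S  = sum((phi * (s$SO4 + s$HS) + so$Pyr) * dx),
    Fe = sum((phi * s$Fe2 + so$FeOX + so$Goe + so$Pyr) * dx),
    Ca = sum((phi * s$Ca + 0.9 * so$CC) * dx),
    Mg = sum((phi * s$Mg + 0.1 * so$CC) * dx),
    N  = sum((phi * s$NH4 + (16 / 106) * so$POM) * dx))
}

test_that("the reaction network conserves S, Fe, Ca, Mg and N in a closed box", {
  state <- scenario_initial_state()
  net <- reaction_network()
  tot0 <- elemental_totals(state)
  for (i in 1:200) {
    state <- degrade_organic_matter(state, net, 0.002)
    state <- precipitate_minerals(state, net, 0.002)
  }
  tot1 <- elemental_totals(state)
  expect_true(all(abs(tot1 - tot0) / tot0 < 1e-6))
  # something actually happened
  expect_gt(sum(state$solids$Pyr), 0)
})

test_that("organic-matter degradation honours its switches and scales", {
  net <- reaction_network()
  # no organic matter, no degradation products
  st0 <- scenario_initial_state()
  st0$solids$POM[] <- 0; st0$solutes$Glu[] <- 0; st0$solutes$Ac[] <- 0
  st0$solutes$H2[] <- 0
  st1 <- degrade_organic_matter(st0, net, 0.01)
  expect_equal(st1$solutes$NH4, st0$solutes$NH4)
  expect_equal(st1$solutes$Ac, st0$solutes$Ac)
  # methanogenesis is off wherever sulfate exceeds its threshold
  st2 <- scenario_initial_state()
  st2$solutes$SO4[] <- 10; st2$solutes$CH4[] <- 0
  st2$solutes$Ac[] <- 1; st2$solutes$H2[] <- 0.01
  net2 <- reaction_network(k_aom = 0)
  st3 <- degrade_organic_matter(st2, net2, 0.01)
  expect_true(all(st3$solutes$CH4 == 0))
  # ammonium released over half a year stays below 3% of the observed scale
  st4 <- scenario_initial_state()
  st4$solutes$NH4[] <- 0
  for (i in 1:50) st4 <- degrade_organic_matter(st4, net, 0.01)
  expect_lt(max(st4$solutes$NH4), 0.03 * 0.5)
})

test_that("mineral sinks respect saturation, stoichiometry and mass balance", {
  net <- reaction_network()
  # undersaturated alkalinity: no carbonate forms
  st <- scenario_initial_state()
  st$solutes$TA[] <- net$TA_sat - 1
  st1 <- precipitate_minerals(st, net, 0.05)
  expect_true(all(st1$solids$CC == 0))
  # iron-sulfide sink removes Fe and HS in its 1:1 stoichiometric ratio
  st$solutes$Fe2[] <- 0.05; st$solutes$HS[] <- 1
  st$solids$FeOX[] <- 0; st$solids$Goe[] <- 0
  st2 <- precipitate_minerals(st, net, 0.001)
  dfe <- st$solutes$Fe2 - st2$solutes$Fe2
  dhs <- st$solutes$HS - st2$solutes$HS
  expect_equal(dfe, dhs, tolerance = 1e-10)
  # closed box: calcium removed equals calcium bound in Mg-calcite
  st3 <- scenario_initial_state()
  st3$solutes$TA[] <- 30
  ca0 <- sum(st3$column$porosity * st3$solutes$Ca * st3$column$dx)
  for (i in 1:100) st3 <- precipitate_minerals(st3, net, 0.01)
  ca1 <- sum(st3$column$porosity * st3$solutes$Ca * st3$column$dx)
  cc <- sum(0.9 * st3$solids$CC * st3$column$dx)
  expect_equal(ca0 - ca1, cc, tolerance = 1e-8 * ca0)
})

test_that("profile shapes are classified as their generating families", {
  z <- seq(0.05, 2, length.out = 40)
  # strictly linear: smooth gradient
  expect_identical(classify_profile_shape(z, 28 - 10 * z)$classification,
                   "smooth-gradient")
  # constructed flat-then-steep: kink at the breakpoint
  prof <- ifelse(z < 0.8, 28, 28 - 25 * (z - 0.8))
  shp <- classify_profile_shape(z, pmax(prof, 0))
  expect_identical(shp$classification, "seawater-flat-then-kink")
  expect_equal(shp$kink_depth, 0.8, tolerance = 0.1)
  # census oracle: the sign pattern of the analytic second derivative
  # determines the expected family for smooth parametric profiles
  set.seed(123)
  for (i in 1:100) {
    a2 <- runif(1, -1, 1)
    fam <- sample(c("quad", "line", "sigmoid"), 1)
    if (fam == "line") {
      y <- 5 + runif(1, -10, 10) * z
      expected <- "smooth-gradient"
    } else if (fam == "quad") {
      a2 <- sign(a2) * runif(1, 0.3, 1)
      y <- 10 + 2 * z + a2 * 10 * z^2
      # field convention: positive d2C/dz2 is concave-down
      expected <- if (a2 > 0) "concave-down" else "concave-up"
    } else {
      y <- 10 / (1 + exp(-(z - 1) / runif(1, 0.15, 0.3)))
      expected <- "S-shaped"
    }
    got <- classify_profile_shape(z, y, zero_tol = -Inf)$classification
    expect_identical(got, expected)
  }
  expect_error(classify_profile_shape(z[1:5], z[1:5]), "at least 8")
})

test_that("an elevated methane flux imprints a kink while ammonium is untouched", {
  sc <- run_scenario(scenario_spec("Scen4"))
  z <- sc$column$cell_centres
  sel <- z <= 2
  shp <- classify_profile_shape(z[sel], sc$state$solutes$SO4[sel])
  expect_identical(shp$classification, "seawater-flat-then-kink")
  nh4dev <- max(abs(sc$state$solutes$NH4[sel] - sc$control$solutes$NH4[sel])) /
    max(sc$control$solutes$NH4[sel])
  expect_lt(nh4dev, 0.05)
  # deflection of the other constrained solutes is concentrated below the kink
  for (nm in c("HS", "TA", "Ca")) {
    above <- z < shp$kink_depth - 0.2
    below <- z >= shp$kink_depth & z <= 2
    d_above <- max(abs(sc$state$solutes[[nm]][above] - sc$control$solutes[[nm]][above]))
    d_below <- max(abs(sc$state$solutes[[nm]][below] - sc$control$solutes[[nm]][below]))
    expect_gt(d_below, 5 * d_above)
  }
})

test_that("seawater intrusion dilutes ammonium in the intruded zone", {
  sc <- run_scenario(scenario_spec("Scen1"))
  z <- sc$column$cell_centres
  intruded <- z <= 0.25
  expect_lt(mean(sc$state$solutes$NH4[intruded]),
            0.5 * mean(sc$control$solutes$NH4[intruded]))
})

test_that("upward advection with a strong source makes an S-shaped sulfate profile", {
  sc <- run_scenario(scenario_spec("Scen5"), control = FALSE)
  z <- sc$column$cell_centres; sel <- z <= 2
  expect_identical(classify_profile_shape(z[sel], sc$state$solutes$SO4[sel])$classification,
                   "S-shaped")
  expect_identical(classify_profile_shape(z[sel], sc$state$solutes$Ca[sel])$classification,
                   "concave-down")
})
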