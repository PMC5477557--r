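make_state <- function(n = 50, dx = 0.02, conc = 0, porosity = 0.7,
                       upper = list(type = "no-flux", value = 0),
                       lower = list(type = "no-flux", value = 0)) {
  col <- sediment_column(n * dx, dx, porosity)
  field_state(col, conc, upper_bc = upper, lower_bc = lower)
}

test_that("Crank-Nicolson step honours trivial limits", {
  st <- make_state(conc = runif(50, 1, 5))
  # zero diffusivity: state unchanged except time
  st2 <- cn_diffusion_step(st, D_s = 0, dt = 0.1)
  expect_identical(st2$concentrations, st$concentrations)
  expect_equal(st2$time, 0.1)
  # uniform field with no-flux ends is an equilibrium
  stu <- make_state(conc = 3.7)
  for (i in 1:20) stu <- cn_diffusion_step(stu, D_s = 0.02, dt = 0.05)
  expect_equal(stu$concentrations, rep(3.7, 50), tolerance = 1e-13)
  expect_error(cn_diffusion_step(st, 0.01, dt = -1), "dt")
})

erfc <- function(x) 2 * pnorm(x * sqrt(2), lower.tail = FALSE)

test_that("fixed-top diffusion matches the erfc semi-infinite solution", {
  D <- 0.01; C0 <- 10
  run_erfc <- function(dx, dt, t_end = 1) {
    col <- sediment_column(2, dx, 1)
    st <- field_state(col, 0, upper_bc = list(type = "fixed-value", value = C0))
    for (i in seq_len(round(t_end / dt))) st <- cn_diffusion_step(st, D, dt)
    st
  }
  st <- run_erfc(0.01, 0.005)
  z <- st$column$cell_centres
  exact <- C0 * erfc(z / (2 * sqrt(D * 1)))
  sel <- exact > 0.05 * C0    # compare where the signal is appreciable
  expect_lt(max(abs(st$concentrations[sel] - exact[sel])) / C0, 0.01)

  # grid refinement: halving dx and dt improves the error at better than
  # first order (second order expected in space)
  err <- function(stx) {
    zx <- stx$column$cell_centres
    ex <- C0 * erfc(zx / (2 * sqrt(D)))
    sqrt(mean((stx$concentrations - ex)^2))
  }
  e1 <- err(run_erfc(0.04, 0.02))
  e2 <- err(run_erfc(0.02, 0.01))
  expect_gte(log2(e1 / e2), 1.8)
})

test_that("discrete maximum principle holds for random pure-diffusion runs", {
  set.seed(42)
  for (rep in 1:5) {
    conc <- runif(40, 0, 8)
    top <- runif(1, 0, 8)
    st <- make_state(n = 40, conc = conc,
                     upper = list(type = "fixed-value", value = top))
    hi <- max(conc, top); lo <- min(conc, top)
    # r = D dt/dx^2 = 1: within the scheme's positivity range
    for (i in 1:50) {
      st <- cn_diffusion_step(st, D_s = 0.05, dt = 0.008)
      expect_lte(max(st$concentrations), hi + 1e-12)
      expect_gte(min(st$concentrations), lo - 1e-12)
    }
    # far beyond it the scheme stays stable (bounded), the signature of the
    # unconditionally stable implicit discretization
    for (i in 1:20) st <- cn_diffusion_step(st, D_s = 0.05, dt = 0.5)
    expect_lte(max(abs(st$concentrations)), hi * 1.001)
  }
})

test_that("no-flux diffusion conserves the inventory to 1e-10", {
  set.seed(7)
  st <- make_state(n = 60, conc = runif(60, 0, 5), porosity = runif(60, 0.4, 0.9))
  m0 <- field_inventory(st)
  for (i in 1:200) st <- cn_diffusion_step(st, 0.03, 0.05)
  expect_lt(abs(field_inventory(st) - m0) / m0, 1e-10)
})

test_that("upwind advection shifts, bounds variation and respects CFL", {
  col <- sediment_column(1, 0.1, 0.7)
  hat <- c(0, 0, 0, 5, 5, 5, 0, 0, 0, 0)
  st <- field_state(col, hat)
  # v*dt exactly one cell: exact shift (CFL = 1 upwind is the shift operator)
  st1 <- advection_step(st, velocity = 1, dt = 0.1, inflow = 0)
  expect_equal(st1$concentrations, c(0, hat[-10]), tolerance = 1e-14)
  # total variation does not increase for a partial-cell step
  st2 <- advection_step(st, velocity = 1, dt = 0.04, inflow = 0)
  tv <- function(x) sum(abs(diff(x)))
  expect_lte(tv(st2$concentrations), tv(hat) + 1e-12)
  # identity at v = 0
  expect_identical(advection_step(st, 0, 0.1)$concentrations, hat)
  # interior mass conservation (inflow 0, nothing leaves yet)
  expect_equal(sum(st2$concentrations), sum(hat), tolerance = 1e-12)
  expect_error(advection_step(st, velocity = 5, dt = 0.1), "CFL")
})

test_that("operator-split kinetics clip, count and couple stoichiometrically", {
  col <- sediment_column(1, 0.1, 0.7)
  states <- list(a = field_state(col, 2), b = field_state(col, 5))
  # zero rates: identity
  s0 <- apply_kinetics(states, function(cc) list(a = 0 * cc$a, b = 0 * cc$b), 0.1)
  expect_identical(s0$a$concentrations, states$a$concentrations)
  # constant sink
  s1 <- apply_kinetics(states, function(cc) list(a = rep(-3, 10)), 0.1)
  expect_equal(s1$a$concentrations, rep(2 - 0.3, 10))
  # 1:1 coupled sink removes equal amounts
  rate <- function(cc) { r <- aom_rate(cc$a, cc$b); list(a = -r, b = -r) }
  s2 <- apply_kinetics(states, rate, 0.05)
  expect_equal(2 - s2$a$concentrations, 5 - s2$b$concentrations, tolerance = 1e-14)
  # undershoot clips to zero and is counted
  s3 <- apply_kinetics(states, function(cc) list(a = rep(-100, 10)), 0.1)
  expect_true(all(s3$a$concentrations == 0))
  expect_identical(s3$a$clip_count, 10L)
  expect_error(apply_kinetics(states, function(cc) list(a = rep(NaN, 10)), 0.1),
               "kinetics")
})
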