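#' Kinetic parameters of the simplified diagenesis network
#'
#' The multi-species screening model replaces a full
#' thermodynamic-database reactive-transport engine with Monod-type rate
#' laws.  Organic matter degrades in two steps (hydrolysis to a
#' glucose-equivalent, fermentation to acetate + H2); acetate and H2 fuel
#' sulfate reduction and methanogenesis, with sulfate reduction switched off
#' where dissolved Fe2+ exceeds 0.4 umol per litre and methanogenesis
#' switched off where sulfate exceeds 0.4 mol m-3; AOM couples methane and
#' sulfate; Fe-oxide reduction and goethite dissolution source Fe2+; Mg-calcite
#' and iron-sulfide (FeS-equivalent, the pyrite precursor) precipitation
#' remove TA/Ca/Mg and Fe/sulfide.  Alkalinity is a
#' transported pseudo-solute updated by reaction stoichiometry.  Rate
#' constants default to values that let an elevated methane flux deflect the
#' porewater profiles within a few years at the 3-m scenario geometry; all
#' are exposed here.
#'
#' @param k_hyd Hydrolysis rate of particulate organic matter, yr-1.
#' @param N_C Ammonium release ratio per carbon hydrolysed.
#' @param k_fer Fermentation rate constant, yr-1.
#' @param k_asr,k_hsr Acetoclastic / hydrogenotrophic sulfate-reduction rate
#'   constants, (mol m-3)-1 yr-1 scale.
#' @param k_amg,k_hmg Methanogenesis rate constants.
#' @param k_aom Maximum AOM rate, mol m-3 yr-1.
#' @param K_so4,K_ch4 AOM half-saturation constants, mol m-3.
#' @param K_so4_sr Sulfate half-saturation of sulfate reduction.
#' @param K_h2 H2 half-saturation of iron reduction.
#' @param fe_inhibition Dissolved-iron threshold above which sulfate
#'   reduction is inhibited, mol m-3 (0.4 uM = 4e-4).
#' @param so4_inhibition Sulfate threshold above which methanogenesis is
#'   inhibited, mol m-3.
#' @param k_feox,k_goe Fe-oxyhydroxide / goethite reduction rate constants.
#' @param k_cc Mg-calcite precipitation constant, yr-1.
#' @param TA_sat Alkalinity threshold for carbonate precipitation, mol m-3.
#' @param k_py Pyrite precipitation constant.
#' @return List of class `"reaction_network"`.
#' @export
reaction_network <- function(k_hyd = 1e-4, N_C = 16 / 106, k_fer = 30,
                             k_asr = 10, k_hsr = 50, k_amg = 0.5, k_hmg = 5,
                             k_aom = 50, K_so4 = 0.5, K_ch4 = 5,
                             K_so4_sr = 0.5, K_h2 = 1e-3,
                             fe_inhibition = 4e-4, so4_inhibition = 0.4,
                             k_feox = 2, k_goe = 2e-5,
                             k_cc = 0.02, TA_sat = 8, k_py = 100) {
  structure(as.list(environment()), class = "reaction_network")
}

.SOLUTES <- c("SO4", "HS", "TA", "Fe2", "Ca", "Mg", "NH4", "CH4", "Ac", "H2", "Glu")
.SOLIDS  <- c("POM", "FeOX", "Goe", "CC", "Pyr")

# seawater / depositional boundary values (mol m-3 porewater; solids mol m-3 bulk)
.SEAWATER <- c(SO4 = 28, HS = 0, TA = 2.3, Fe2 = 0, Ca = 10.3, Mg = 53,
               NH4 = 0, CH4 = 0, Ac = 0, H2 = 0, Glu = 0)
.SURFACE_SOLIDS <- c(POM = 300, FeOX = 50, Goe = 5, CC = 0, Pyr = 0)

#' Declarative description of one diagenetic scenario
#'
#' The five screening scenarios for kink-type porewater profiles on a 3-m
#' column (200 cells over the upper 2 m plus a 1-m methane-generator cell):
#' \describe{
#'   \item{Scen1}{downward seawater intrusion at 1 m yr-1 for 0.25 yr}
#'   \item{Scen2}{top 0.3 m homogenized to seawater composition with
#'     oxidized (Fe-oxide-rich) solids, then 0.5 yr of relaxation}
#'   \item{Scen3}{a 0.275-m low-porosity (0.5) cap deposited on top, 900 yr}
#'   \item{Scen4}{elevated methane source in the generator cell, 2.5 yr}
#'   \item{Scen5}{upward advection at 1 m yr-1 plus a high methane source,
#'     0.7 yr, with a lowered initial ammonium profile}
#' }
#'
#' @param id `"Scen1"` .. `"Scen5"`.
#' @param duration Simulated years (scenario defaults when `NULL`).
#' @param dt Master time step in years (scenario defaults when `NULL`).
#' @param ch4_source Generator-cell dissolved methane, mol m-3 (base value
#'   for unperturbed scenarios, elevated for Scen4/Scen5).
#' @param network A [reaction_network()].
#' @param temperature_C Temperature for diffusivities (1.3 degC).
#' @param formation_factor Porosity correction for diffusivities (1.5).
#' @param sedimentation_rate Burial velocity of solids, m yr-1 (3.4e-4).
#' @return Object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(id = c("Scen1", "Scen2", "Scen3", "Scen4", "Scen5"),
                          duration = NULL, dt = NULL, ch4_source = NULL,
                          network = reaction_network(), temperature_C = 1.3,
                          formation_factor = 1.5,
                          sedimentation_rate = 3.4e-4) {
  id <- match.arg(id)
  defaults <- list(
    Scen1 = list(duration = 0.25, dt = 0.001, ch4_source = 30,  advection = 1),
    Scen2 = list(duration = 0.5,  dt = 0.002, ch4_source = 30,  advection = 0),
    Scen3 = list(duration = 900,  dt = 0.02,  ch4_source = 30,  advection = 0),
    Scen4 = list(duration = 2.5,  dt = 0.002, ch4_source = 300, advection = 0),
    Scen5 = list(duration = 0.7,  dt = 0.001, ch4_source = 300, advection = -1))[[id]]
  structure(list(id = id,
                 duration = if (is.null(duration)) defaults$duration else duration,
                 dt = if (is.null(dt)) defaults$dt else dt,
                 ch4_source = if (is.null(ch4_source)) defaults$ch4_source else ch4_source,
                 advection = defaults$advection,
                 network = network, temperature_C = temperature_C,
                 formation_factor = formation_factor,
                 sedimentation_rate = sedimentation_rate),
            class = "scenario_spec")
}

# the scenario grid: 200 x 0.01 m + one 1-m generator cell
.scenario_column <- function(porosity = 0.7) {
  sediment_column(dx = c(rep(0.01, 200), 1), porosity = porosity)
}

#' Baseline quasi-steady seepage state of the scenario model
#'
#' A constructed initial state representative of an active seep: linear
#' seawater-to-zero sulfate down to the initial SMTZ, methane rising below
#' it, a sulfide maximum at the SMTZ, alkalinity and ammonium increasing with
#' depth, calcium/magnesium drawn down, dissolved iron confined to the
#' surface iron-reduction zone, and solids (organic matter, Fe-oxides,
#' goethite) with an oxidized surface layer.  Used as the starting point
#' (and, run unperturbed, the control) of all five scenarios.
#'
#' @param column Scenario column (default geometry).
#' @param smtz0 Initial SMTZ depth, m.
#' @param ch4_deep Dissolved methane at the column base, mol m-3.
#' @param nh4_deep Ammonium at the column base, mol m-3.
#' @return Object of class `"scenario_state"`.
#' @export
scenario_initial_state <- function(column = .scenario_column(), smtz0 = 1.6,
                                   ch4_deep = 30, nh4_deep = 0.6) {
  z <- column$cell_centres
  L <- column$length
  sol <- list(
    SO4 = pmax(.SEAWATER[["SO4"]] * (1 - z / smtz0), 0),
    HS  = pmax(3 * (1 - abs(z - smtz0) / smtz0), 0),
    TA  = 2.3 + (30 - 2.3) * pmin(z / smtz0, 1 + 0.2 * (z - smtz0) / L),
    Fe2 = 0.05 * exp(-z / 0.05),
    Ca  = 10.3 - 4.5 * pmin(z / smtz0, 1),
    Mg  = 53 - 4 * pmin(z / smtz0, 1),
    NH4 = nh4_deep * z / L,
    CH4 = pmax(ch4_deep * (z - smtz0) / (L - smtz0), 0),
    Ac  = rep(1e-3, column$n_cells),
    H2  = rep(1e-5, column$n_cells),
    Glu = rep(1e-3, column$n_cells))
  solids <- list(
    POM  = rep(.SURFACE_SOLIDS[["POM"]], column$n_cells),
    FeOX = .SURFACE_SOLIDS[["FeOX"]] * exp(-z / 0.03) + 0.002,
    Goe  = ifelse(z > 0.5, 20, 2),
    CC   = rep(0, column$n_cells),
    Pyr  = rep(0, column$n_cells))
  structure(list(column = column, solutes = sol, solids = solids, time = 0,
                 clip_events = 0L),
            class = "scenario_state")
}

#' @export
print.scenario_state <- function(x, ...) {
  cat(sprintf("scenario state at t = %.3g yr: SMTZ %.2f mbsf, %d solutes, %d solids\n",
              x$time, smtz_depth(x$column$cell_centres, x$solutes$SO4),
              length(x$solutes), length(x$solids)))
  invisible(x)
}

# reaction rates (bulk-volume basis, mol m-3 bulk yr-1) for every reaction
.scenario_rates <- function(state, net) {
  s <- state$solutes; so <- state$solids
  phi <- state$column$porosity
  I_fe <- as.numeric(s$Fe2 <= net$fe_inhibition)
  I_so4 <- as.numeric(s$SO4 <= net$so4_inhibition)
  mono_so4 <- s$SO4 / (net$K_so4_sr + s$SO4)
  list(
    hyd  = net$k_hyd * so$POM,
    fer  = net$k_fer * phi * s$Glu,
    asr  = net$k_asr * phi * s$Ac * mono_so4 * I_fe,
    hsr  = net$k_hsr * phi * s$H2 * mono_so4 * I_fe,
    amg  = net$k_amg * phi * s$Ac * I_so4,
    hmg  = net$k_hmg * phi * s$H2 * I_so4,
    aom  = net$k_aom * phi * s$SO4 / (net$K_so4 + s$SO4) * s$CH4 / (net$K_ch4 + s$CH4),
    feox = net$k_feox * so$FeOX * s$H2 / (net$K_h2 + s$H2),
    goe  = net$k_goe * so$Goe * s$H2 / (net$K_h2 + s$H2),
    cc   = net$k_cc * phi * pmax(0, s$TA - net$TA_sat) * s$Ca / (s$Ca + 0.1),
    py   = net$k_py * phi * s$Fe2 * s$HS)
}

# stoichiometry of the network, bulk-volume basis; one named coefficient
# vector per reaction.  NH4 release tracks the N:C ratio (set at build time).
.scenario_stoich <- function(N_C) {
  list(
    hyd  = c(Glu = 1 / 6, NH4 = N_C, POM = -1),
    fer  = c(Glu = -1, Ac = 2, H2 = 4),
    asr  = c(Ac = -1, SO4 = -1, HS = 1, TA = 2),
    hsr  = c(H2 = -4, SO4 = -1, HS = 1, TA = 2),
    amg  = c(Ac = -1, CH4 = 1),
    hmg  = c(H2 = -4, CH4 = 1),
    aom  = c(SO4 = -1, CH4 = -1, HS = 1, TA = 2),
    feox = c(FeOX = -2, H2 = -1, Fe2 = 2, TA = 4),
    goe  = c(Goe = -2, H2 = -1, Fe2 = 2, TA = 4),
    cc   = c(TA = -2, Ca = -0.9, Mg = -0.1, CC = 1),
    py   = c(Fe2 = -1, HS = -1, TA = -2, Pyr = 1))
}

# Apply the network for one explicit step.  Reactions consuming a pool that
# would be driven negative are scaled down (whole reactions, so the
# stoichiometry and hence elemental balance stay exact); a few passes of
# this availability limiting resolve chained deficits.
.apply_network <- function(state, net, dt) {
  rl <- .scenario_rates(state, net)
  R <- do.call(cbind, rl)                       # cells x reactions
  stM <- .stoich_matrix(net$N_C)                # species x reactions
  phi <- state$column$porosity
  n <- nrow(R)
  nsol <- length(.SOLUTES)
  A <- cbind(matrix(unlist(state$solutes, use.names = FALSE), n) * phi,
             matrix(unlist(state$solids, use.names = FALSE), n))
  Mneg <- t(pmax(-stM, 0))                      # reactions x species
  clip <- 0L
  for (pass in 1:3) {
    cons <- dt * (R %*% Mneg)                   # cells x species
    f <- pmax(A, 0) / pmax(cons, 1e-300)
    f[cons <= 0] <- 1
    f[f > 1] <- 1
    if (!any(f < 1)) break
    for (j in seq_len(ncol(R))) {
      cs <- which(stM[, j] < 0)
      if (length(cs) == 0) next
      fj <- f[, cs[1]]
      for (c2 in cs[-1]) fj <- pmin(fj, f[, c2])
      if (any(fj < 1)) { R[, j] <- R[, j] * fj; clip <- clip + sum(fj < 1) }
    }
  }
  delta <- dt * (R %*% t(stM))                  # cells x species
  for (i in seq_along(.SOLUTES))
    state$solutes[[.SOLUTES[i]]] <- pmax(state$solutes[[.SOLUTES[i]]] +
                                           delta[, i] / phi, 0)
  for (i in seq_along(.SOLIDS))
    state$solids[[.SOLIDS[i]]] <- pmax(state$solids[[.SOLIDS[i]]] +
                                         delta[, nsol + i], 0)
  state$clip_events <- state$clip_events + clip
  state
}

# stoichiometry as a (species x reaction) matrix in the fixed species order
# (cached; rebuilt only when the N:C ratio changes)
.stoich_cache <- new.env(parent = emptyenv())
.stoich_matrix <- function(N_C) {
  key <- format(N_C, digits = 15)
  if (!is.null(.stoich_cache[[key]])) return(.stoich_cache[[key]])
  st <- .scenario_stoich(N_C)
  sp <- c(.SOLUTES, .SOLIDS)
  M <- matrix(0, length(sp), length(st), dimnames = list(sp, names(st)))
  for (j in names(st)) M[names(st[[j]]), j] <- st[[j]]
  .stoich_cache[[key]] <- M
  M
}

#' Organic-matter degradation cascade, one explicit step
#'
#' Hydrolysis of particulate organic matter to a glucose-equivalent,
#' fermentation to acetate + H2 (ammonium released at the N:C ratio),
#' acetoclastic and hydrogenotrophic sulfate reduction (inhibited above the
#' dissolved-iron threshold) and methanogenesis (inhibited above the sulfate
#' threshold), plus AOM.  Exposed for testing; [run_scenario()] applies it as
#' part of the full network.
#'
#' @param state A `"scenario_state"`.
#' @param net A [reaction_network()].
#' @param dt Time step, years.
#' @return Updated state.
#' @export
degrade_organic_matter <- function(state, net = reaction_network(), dt) {
  net$k_feox <- 0; net$k_goe <- 0; net$k_cc <- 0; net$k_py <- 0
  .apply_network(state, net, dt)
}

#' Mineral precipitation/dissolution, one explicit step
#'
#' Mg-calcite precipitation above the alkalinity saturation threshold
#' (consuming TA, Ca and Mg at 2 : 0.9 : 0.1), pyrite precipitation from
#' Fe2+ and sulfide, and Fe2+ release from Fe-oxyhydroxide reduction and
#' goethite dissolution.
#'
#' @inheritParams degrade_organic_matter
#' @return Updated state.
#' @export
precipitate_minerals <- function(state, net = reaction_network(), dt) {
  net$k_hyd <- 0; net$k_fer <- 0; net$k_asr <- 0; net$k_hsr <- 0
  net$k_amg <- 0; net$k_hmg <- 0; net$k_aom <- 0
  .apply_network(state, net, dt)
}

# one full operator-split step: diffusion -> advection -> kinetics
.scenario_step <- function(state, spec, Ds, dt, fluid_velocity = 0) {
  col <- state$column
  for (nm in .SOLUTES) {
    Dv <- Ds[[nm]]
    if (length(Dv) == 1) Dv <- rep(Dv, col$n_cells)
    state$solutes[[nm]] <- pmax(cn_step_general(
      state$solutes[[nm]], col$porosity, Dv, col$dx, dt,
      0L, .SEAWATER[[nm]], .SEAWATER[[nm]], 1L, 0, 0), 0)
  }
  if (fluid_velocity != 0) {
    for (nm in .SOLUTES) {
      inflow <- if (fluid_velocity > 0) .SEAWATER[[nm]]
                else state$solutes[[nm]][col$n_cells]
      state$solutes[[nm]] <- upwind_step(state$solutes[[nm]], fluid_velocity,
                                         col$dx, dt, inflow)
    }
  }
  if (spec$sedimentation_rate > 0) {
    for (nm in .SOLIDS)
      state$solids[[nm]] <- upwind_step(state$solids[[nm]],
                                        spec$sedimentation_rate, col$dx, dt,
                                        .SURFACE_SOLIDS[[nm]])
  }
  # methane generator cell: held at the source strength
  state$solutes$CH4[col$n_cells] <- spec$ch4_source
  state <- .apply_network(state, spec$network, dt)
  state$time <- state$time + dt
  state
}

#' Run one diagenetic scenario (and its unperturbed control)
#'
#' Integrates the simplified transport-reaction network for the scenario's
#' duration, alongside a control run from the same initial state with no
#' perturbation (base methane source, no advection, no cap, no
#' homogenization).  Profile deflections are judged against the control.
#'
#' @param spec A [scenario_spec()].
#' @param initial A `"scenario_state"`; default [scenario_initial_state()].
#' @param control Logical: also run the control (default `TRUE`).
#' @return Object of class `"diagenetic_scenario"` with `state` (final
#'   perturbed state), `control` (final control state or `NULL`), `spec`,
#'   and `column`.
#' @export
run_scenario <- function(spec, initial = NULL, control = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"))
  base_spec <- spec
  base_spec$ch4_source <- scenario_spec(spec$id)$ch4_source
  if (spec$id %in% c("Scen4", "Scen5")) base_spec$ch4_source <- 30
  base_spec$advection <- 0
  if (is.null(initial)) {
    initial <- switch(spec$id,
      # the methane-pulse scenario starts from a weak-seepage state (deep
      # SMTZ, near-seawater sulfate over the whole window) so the pulse can
      # imprint a kink on an otherwise smooth background
      Scen4 = scenario_initial_state(smtz0 = 9, ch4_deep = 0),
      Scen5 = scenario_initial_state(nh4_deep = 0.2),
      scenario_initial_state())
  }
  state <- initial
  col <- state$column
  # scenario-specific perturbations of the initial condition
  if (spec$id == "Scen2") {
    top <- col$cell_centres < 0.3
    for (nm in .SOLUTES) state$solutes[[nm]][top] <- .SEAWATER[[nm]]
    state$solids$FeOX[top] <- 100      # oxidized mass-transport deposit
    state$solids$Pyr[top] <- 0
  }
  if (spec$id == "Scen3") {
    ncap <- sum(cumsum(col$dx) <= 0.275 + 1e-9)
    cap <- seq_len(max(ncap, 1))
    state$column$porosity[cap] <- 0.5
    for (nm in .SOLUTES) state$solutes[[nm]][cap] <- .SEAWATER[[nm]]
    state$solids$POM[cap] <- .SURFACE_SOLIDS[["POM"]]
    state$solids$FeOX[cap] <- .SURFACE_SOLIDS[["FeOX"]]
  }
  Ds <- sapply(c(SO4 = "sulfate", HS = "sulfide", TA = "alkalinity",
                 Fe2 = "iron2", Ca = "calcium", Mg = "magnesium",
                 NH4 = "ammonium", CH4 = "methane", Ac = "acetate",
                 H2 = "hydrogen", Glu = "glucose"),
               function(sp) formation_factor_diffusivity(
                 free_solution_diffusivity(sp, spec$temperature_C),
                 spec$formation_factor), simplify = FALSE)
  n_steps <- as.integer(round(spec$duration / spec$dt))
  v <- spec$advection
  if (v != 0 && abs(v) * spec$dt > min(col$dx))
    stop("CFL violation in fluid advection: reduce dt below dx/|v|")
  for (k in seq_len(n_steps))
    state <- .scenario_step(state, spec, Ds, spec$dt, fluid_velocity = v)
  ctrl <- NULL
  if (control) {
    ctrl <- initial
    ctrl$column <- col          # control keeps the unperturbed porosity
    for (k in seq_len(n_steps))
      ctrl <- .scenario_step(ctrl, base_spec, Ds, spec$dt, fluid_velocity = 0)
  }
  structure(list(state = state, control = ctrl, spec = spec, column = col),
            class = "diagenetic_scenario")
}

#' @export
print.diagenetic_scenario <- function(x, ...) {
  cat(sprintf("%s: %.3g yr simulated; final SMTZ %.2f mbsf (control %.2f)\n",
              x$spec$id, x$spec$duration,
              smtz_depth(x$column$cell_centres, x$state$solutes$SO4),
              if (is.null(x$control)) NA else
                smtz_depth(x$column$cell_centres, x$control$solutes$SO4)))
  invisible(x)
}

#' @export
plot.diagenetic_scenario <- function(x, solutes = c("SO4", "TA", "Ca", "NH4"),
                                     max_depth = 2, ...) {
  old <- graphics::par(mfrow = c(1, length(solutes)))
  on.exit(graphics::par(old))
  z <- x$column$cell_centres; sel <- z <= max_depth
  for (nm in solutes) {
    rng <- range(x$state$solutes[[nm]][sel],
                 if (!is.null(x$control)) x$control$solutes[[nm]][sel])
    plot(x$state$solutes[[nm]][sel], z[sel], type = "l", ylim = c(max_depth, 0),
         xlim = rng, xlab = paste(nm, "(mol m-3)"), ylab = "depth (mbsf)")
    if (!is.null(x$control))
      graphics::lines(x$control$solutes[[nm]][sel], z[sel], lty = 2)
  }
  invisible(x)
}

#' Classify the shape of a porewater profile
#'
#' Deterministic shape classification from fitted segments, using the
#' field's plotted-profile convention (depth increasing downward): a
#' profile that is flat near the seafloor and steepens with depth is
#' `"concave-up"` (the kink-type family), one that is steep near the
#' seafloor and flattens with depth is `"concave-down"`, a near-flat
#' shallow segment over a much steeper quasi-linear one is
#' `"seawater-flat-then-kink"`, a sigmoidal profile whose curvature changes
#' sign is `"S-shaped"`, and a profile with no significant curvature is
#' `"smooth-gradient"`.  The exhausted tail beneath the SMTZ (values below
#' `zero_tol`) is excluded before fitting.
#'
#' @param depth,conc Profile coordinates, >= 8 points.
#' @param flat_slope_max Maximum shallow-segment |slope| for a kink,
#'   mol m-3 m-1 (raw units).
#' @param min_steepening Required deep/shallow |slope| ratio for a kink.
#' @param curv_tol Curvature threshold on range-normalized coordinates.
#' @param fit_tol Relative residual threshold for segment fits.
#' @param zero_tol Concentration level marking the exhausted tail.
#' @return List of class `"profile_shape"`: `classification`, `kink_depth`
#'   (`NA` unless kinked).
#' @export
classify_profile_shape <- function(depth, conc, flat_slope_max = 8,
                                   min_steepening = 2.5, curv_tol = 0.04,
                                   fit_tol = 0.01, zero_tol = 0.4) {
  if (length(depth) < 8) stop("shape error: need at least 8 points")
  out <- function(cl, kd = NA_real_)
    structure(list(classification = cl, kink_depth = kd), class = "profile_shape")
  # drop the exhausted tail beneath the SMTZ (keep one crossing point)
  n_keep <- length(conc)
  if (any(conc < zero_tol)) n_keep <- min(which(conc < zero_tol))
  n_keep <- min(n_keep + 1, length(conc))
  if (n_keep >= 8) { depth <- depth[seq_len(n_keep)]; conc <- conc[seq_len(n_keep)] }
  n <- length(depth)
  rngc <- diff(range(conc))
  if (rngc <= 1e-9) return(out("smooth-gradient"))
  x <- (depth - min(depth)) / diff(range(depth))
  y <- (conc - min(conc)) / rngc
  sst <- sum((y - mean(y))^2)
  lin <- stats::lm.fit(cbind(1, x), y)
  sse_lin <- sum(lin$residuals^2)
  if (sse_lin < fit_tol * sst) return(out("smooth-gradient"))
  # two-segment kink candidate on the trimmed region
  kink <- tryCatch(detect_kink(depth, conc, flat_slope_max, min_steepening,
                               zero_tol = -Inf),
                   error = function(e) NULL)
  if (!is.null(kink)) {
    k <- kink$index
    f1 <- stats::lm.fit(cbind(1, x[1:k]), y[1:k])
    f2 <- stats::lm.fit(cbind(1, x[k:n]), y[k:n])
    sse2 <- sum(f1$residuals^2) + sum(f2$residuals^2)
    # a genuine kink is two quasi-linear segments meeting at a corner: it
    # must beat both the single line and a smooth parabola
    sse_quad <- sum(stats::lm.fit(cbind(1, x, x^2), y)$residuals^2)
    if ((sse2 < 0.35 * sse_lin || sse2 < fit_tol * sst) && sse2 < 0.5 * sse_quad)
      return(out("seawater-flat-then-kink", kink$depth))
  }
  cub <- stats::lm.fit(cbind(1, x, x^2, x^3), y)
  a2 <- cub$coefficients[3]; a3 <- cub$coefficients[4]
  curv0 <- 2 * a2          # curvature (d2C/dz2) at the top
  curv1 <- 2 * a2 + 6 * a3 # at the base of the fitted region
  if (sign(curv0) != sign(curv1) && min(abs(curv0), abs(curv1)) > curv_tol)
    return(out("S-shaped"))
  quad <- stats::lm.fit(cbind(1, x, x^2), y)
  b2 <- quad$coefficients[3]
  # field convention: d2C/dz2 < 0 (steepening with depth) is concave-up
  if (b2 < -curv_tol) return(out("concave-up"))
  if (b2 > curv_tol) return(out("concave-down"))
  out("smooth-gradient")
}

#' @export
print.profile_shape <- function(x, ...) {
  cat("profile shape:", x$classification)
  if (!is.na(x$kink_depth)) cat(sprintf(" (kink at %.2f mbsf)", x$kink_depth))
  cat("\n")
  invisible(x)
}
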