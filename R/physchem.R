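#' seepsim: transport-reaction modelling of methane seepage in marine sediments
#'
#' Dating of methane-pulse onsets from non-steady-state porewater sulfate
#' profiles, conductive heat propagation with gas-hydrate stability
#' assessment, and a simplified early-diagenesis reaction network for
#' screening mechanisms behind "kink-type" porewater profiles.
#'
#' @useDynLib seepsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx optimize rnorm rpois runif sd
#' @importFrom utils modifyList read.csv write.csv
#' @keywords internal
"_PACKAGE"

# Seconds per (365-day) year; fixed so that diffusivities printed in
# m2 yr-1 round-trip exactly from the cm2 s-1 compilation values.
SECONDS_PER_YEAR <- 3.1536e7

# Linear infinite-dilution diffusion coefficients, D = (m0 + m1 * T) 1e-6
# cm2 s-1 with T in degrees C, after the standard marine-diagenesis
# compilation for ions.  The dissolved-gas entries (methane, hydrogen) use
# the same linear form with coefficients calibrated against the bottom-water
# anchor values adopted throughout this package (methane: 0.0301 m2 yr-1 at
# 0.56 degC); glucose and acetate are representative organic-solute values.
.D_COEFS <- list(
  sulfate    = c(4.88,   0.232),
  methane    = c(9.3766, 0.300),
  sulfide    = c(10.4,   0.273),
  calcium    = c(3.60,   0.179),
  magnesium  = c(3.43,   0.144),
  ammonium   = c(9.50,   0.413),
  iron2      = c(3.31,   0.150),
  alkalinity = c(5.06,   0.275),   # bicarbonate carrier
  acetate    = c(4.46,   0.204),
  hydrogen   = c(26.2,   0.750),
  glucose    = c(3.00,   0.150)
)

#' Free-solution diffusion coefficient of a solute in seawater
#'
#' Linear-in-temperature infinite-dilution diffusivities, converted to
#' m2 yr-1 with a 365-day year.  At the bottom-water temperature used for the
#' pulse-dating model (0.56 degC) this gives 0.0158 m2 yr-1 for sulfate and
#' 0.0301 m2 yr-1 for methane.
#'
#' @param species One of `"sulfate"`, `"methane"`, `"sulfide"`, `"calcium"`,
#'   `"magnesium"`, `"ammonium"`, `"iron2"`, `"alkalinity"`, `"acetate"`,
#'   `"hydrogen"`, `"glucose"`.
#' @param temperature_C Temperature in degrees Celsius, within \[-2, 30\].
#' @return Diffusion coefficient in m2 yr-1.
#' @examples
#' free_solution_diffusivity("sulfate", 0.56)
#' @export
free_solution_diffusivity <- function(species, temperature_C) {
  species <- match.arg(species, names(.D_COEFS))
  if (!is.numeric(temperature_C) || any(temperature_C < -2) || any(temperature_C > 30))
    stop("temperature must lie in [-2, 30] degC")
  cf <- .D_COEFS[[species]]
  (cf[1] + cf[2] * temperature_C) * 1e-6 * SECONDS_PER_YEAR * 1e-4
}

#' Porous-medium diffusion coefficient
#'
#' Tortuosity correction `D_s = D / theta^2`.
#'
#' @param D Free-solution diffusivity (any area-per-time unit).
#' @param tortuosity Dimensionless tortuosity, `theta >= 1`.
#' @return Effective diffusivity in the same units as `D`.
#' @export
porous_media_diffusivity <- function(D, tortuosity) {
  if (any(D <= 0)) stop("D must be positive")
  if (any(tortuosity < 1)) stop("invalid tortuosity: theta must be >= 1")
  D / tortuosity^2
}

#' Formation-factor diffusivity correction
#'
#' Alternative porous-medium correction `D_s = D / F` used by the
#' multi-species scenario model, where `F` is the (dimensionless) formation
#' factor applied to the porosity correction (default 1.5).
#'
#' @param D Free-solution diffusivity.
#' @param formation_factor Formation factor `F >= 1`.
#' @return Effective diffusivity.
#' @export
formation_factor_diffusivity <- function(D, formation_factor = 1.5) {
  if (any(D <= 0)) stop("D must be positive")
  if (any(formation_factor < 1)) stop("formation factor must be >= 1")
  D / formation_factor
}

#' Hydrostatic pressure at depth
#'
#' `P(z) = 0.101325 + 0.0101 (water_depth + z)` MPa; no excess pore pressure.
#'
#' @param z Depth below seafloor in m (may be a vector).
#' @param water_depth Water-column depth in m.
#' @return Pressure in MPa.
#' @export
hydrostatic_pressure <- function(z, water_depth = 380) {
  0.101325 + 0.0101 * (water_depth + z)
}

#' Structure-I methane-hydrate equilibrium temperature in seawater
#'
#' Dissociation temperature of structure-I methane hydrate in seawater from
#' the classic marine phase-boundary correlation
#' `1/T = 3.79e-3 - 2.83e-4 log10(P)` (T in K, P in MPa), with a linear
#' freezing-point-style salinity adjustment about the reference salinity 35.
#'
#' @param pressure_MPa Pressure in MPa, within \[1, 20\].
#' @param salinity Practical salinity (default 35).
#' @return Equilibrium temperature in degrees Celsius.
#' @examples
#' hydrate_equilibrium_temperature(hydrostatic_pressure(60, 380))
#' @export
hydrate_equilibrium_temperature <- function(pressure_MPa, salinity = 35) {
  if (any(pressure_MPa < 1) || any(pressure_MPa > 20))
    stop("pressure outside correlation validity [1, 20] MPa")
  TK <- 1 / (3.79e-3 - 2.83e-4 * log10(pressure_MPa))
  # about -0.0314 K per salinity unit: reproduces the ~1.1 K seawater
  # depression relative to pure water at S = 35
  TK - 273.15 - 0.0314 * (salinity - 35)
}

#' Equilibrium pressure of structure-I methane hydrate in seawater
#'
#' Inverse of [hydrate_equilibrium_temperature()]: the dissociation pressure
#' at a given temperature.
#'
#' @param temperature_C Temperature in degrees Celsius.
#' @param salinity Practical salinity.
#' @return Pressure in MPa.
#' @export
hydrate_equilibrium_pressure <- function(temperature_C, salinity = 35) {
  TK <- temperature_C + 273.15 + 0.0314 * (salinity - 35)
  P <- 10^((3.79e-3 - 1 / TK) / 2.83e-4)
  if (any(P < 1) || any(P > 20))
    stop("temperature outside correlation validity")
  P
}

#' Dissolved methane concentration at hydrate equilibrium
#'
#' Methane solubility in seawater coexisting with structure-I hydrate.
#' The dissolved concentration is set by Henry's law at the
#' hydrate-equilibrium (three-phase) pressure for the local temperature:
#' the Bunsen solubility coefficient for methane in seawater (the standard
#' oceanographic temperature/salinity fit) is scaled to the dissociation
#' pressure from [hydrate_equilibrium_pressure()].  Gas-phase non-ideality is
#' neglected by default (a few per cent at these pressures), matching common
#' practice in diagenetic modelling; `fugacity = "virial"` applies a
#' second-virial-coefficient correction.  With `mode = "paper_constant"` the
#' value is pinned to 64 mol m-3, the anchor used by the site calculations.
#'
#' @param temperature_C Temperature in degrees Celsius.
#' @param pressure_MPa Local pressure in MPa (used for validity checking and
#'   the stability-side requirement `P >= P_eq`).
#' @param salinity Practical salinity.
#' @param mode `"correlation"` (default) or `"paper_constant"`.
#' @param fugacity `"ideal"` (default) or `"virial"`.
#' @return Concentration in mol m-3 of porewater (1 mM = 1 mol m-3).
#' @examples
#' methane_solubility(1.25, 3.85)
#' @export
methane_solubility <- function(temperature_C, pressure_MPa, salinity = 35,
                               mode = c("correlation", "paper_constant"),
                               fugacity = c("ideal", "virial")) {
  mode <- match.arg(mode)
  fugacity <- match.arg(fugacity)
  if (mode == "paper_constant") return(64)
  if (any(pressure_MPa < 1) || any(pressure_MPa > 20))
    stop("pressure outside correlation validity [1, 20] MPa")
  TK <- temperature_C + 273.15
  if (any(TK < 271) || any(TK > 293)) stop("temperature outside correlation validity")
  Peq <- hydrate_equilibrium_pressure(temperature_C, salinity)
  Ts <- TK / 100
  ln_beta <- -67.1962 + 99.1624 * (100 / TK) + 27.9015 * log(Ts) +
    salinity * (-0.072909 + 0.041674 * Ts - 0.0064603 * Ts^2)
  beta <- exp(ln_beta)               # L CH4 (STP) per L per atm
  f_atm <- Peq / 0.101325
  if (fugacity == "virial") {
    Bv <- (-105.5 + 0.19 * TK) * 1e-6      # m3 mol-1, methane second virial
    f_atm <- f_atm * exp(Bv * Peq * 1e6 / (8.314 * TK))
  }
  beta / 22.414 * f_atm * 1000       # mol m-3
}

#' Linearized hydrate phase boundary over a sediment column
#'
#' Builds a piecewise-linear (here: linear) equilibrium-temperature profile
#' `T_eq(z)` over the column, anchored exactly at the base-of-GHSZ point
#' (by default 4.05 degC at 60 mbsf).  The slope is the secant of the
#' published correlation between the seafloor and the anchor depth under the
#' hydrostatic pressure convention, unless supplied explicitly.
#'
#' @param water_depth Water depth in m.
#' @param column_depth Column length in m (anchor depth).
#' @param salinity Practical salinity.
#' @param anchor_temperature Equilibrium temperature at `column_depth`
#'   (degC); default 4.05.
#' @param slope Optional slope in degC m-1; computed from the correlation if
#'   `NULL`.
#' @return Object of class `"hydrate_phase_boundary"` with fields
#'   `anchor_depth`, `anchor_temperature`, `slope`, `seafloor_equilibrium_T`,
#'   `water_depth`, `salinity`, and a function `T_eq(z)`.
#' @export
phase_boundary_profile <- function(water_depth = 380, column_depth = 60,
                                   salinity = 35, anchor_temperature = 4.05,
                                   slope = NULL) {
  if (column_depth <= 0) stop("column_depth must be positive")
  if (is.null(slope)) {
    T0 <- hydrate_equilibrium_temperature(hydrostatic_pressure(0, water_depth), salinity)
    T1 <- hydrate_equilibrium_temperature(hydrostatic_pressure(column_depth, water_depth), salinity)
    slope <- (T1 - T0) / column_depth
  }
  if (slope < 0) stop("equilibrium temperature must be non-decreasing with depth")
  anchor_depth <- column_depth
  out <- list(anchor_depth = anchor_depth,
              anchor_temperature = anchor_temperature,
              slope = slope,
              seafloor_equilibrium_T = anchor_temperature - anchor_depth * slope,
              water_depth = water_depth, salinity = salinity)
  out$T_eq <- function(z) anchor_temperature + slope * (z - anchor_depth)
  class(out) <- "hydrate_phase_boundary"
  out
}

#' @export
print.hydrate_phase_boundary <- function(x, ...) {
  cat("Structure-I methane-hydrate phase boundary (linearized)\n")
  cat(sprintf("  anchor: %.2f degC at %.1f mbsf; slope %.4f degC/m\n",
              x$anchor_temperature, x$anchor_depth, x$slope))
  cat(sprintf("  seafloor equilibrium temperature: %.2f degC\n",
              x$seafloor_equilibrium_T))
  invisible(x)
}

#' Geothermal gradient from two temperature anchors
#'
#' @param T_seafloor Seafloor temperature, degC.
#' @param T_base Temperature at `base_depth`, degC.
#' @param base_depth Depth of the deep anchor in m (> 0).
#' @return Gradient in degC m-1.
#' @examples
#' geothermal_gradient(1.44, 4.05, 60) # 0.0435, reported as 0.044
#' @export
geothermal_gradient <- function(T_seafloor, T_base, base_depth) {
  if (!is.numeric(base_depth) || base_depth <= 0)
    stop("invalid geometry: base_depth must be positive")
  (T_base - T_seafloor) / base_depth
}

#' Thermal properties of water-saturated sediment
#'
#' Container for constituent conductivities, heat capacities and densities of
#' porewater (`w`) and dry sediment grains (`s`, quartz by default).
#'
#' @param lambda_w,lambda_s Thermal conductivities, W m-1 K-1.
#' @param C_w,C_s Specific heats, J g-1 K-1.
#' @param rho_w,rho_s Densities, g m-3.
#' @param porosity Volume fraction of porewater.
#' @return Object of class `"thermal_properties"`.
#' @export
thermal_properties <- function(lambda_w = 0.56, lambda_s = 8.05,
                               C_w = 4.2, C_s = 0.73,
                               rho_w = 1.03e6, rho_s = 2.60e6,
                               porosity = 0.7) {
  vals <- c(lambda_w, lambda_s, C_w, C_s, rho_w, rho_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all constituent properties must be strictly positive")
  if (porosity < 0 || porosity > 1) stop("porosity must lie in [0, 1]")
  structure(list(lambda_w = lambda_w, lambda_s = lambda_s, C_w = C_w,
                 C_s = C_s, rho_w = rho_w, rho_s = rho_s,
                 porosity = porosity),
            class = "thermal_properties")
}

#' Bulk thermal diffusivity of the sediment column
#'
#' In `"paper_constant"` mode (the default) returns the fixed bulk value
#' 33.4273 m2 yr-1 to which the heat model is pinned.  In `"computed"` mode a
#' geometric-mean conductivity with volume-weighted volumetric heat capacity
#' is used; this mixing law is not guaranteed to reproduce the pinned
#' constant (see the methods vignette) but honours the single-phase limits.
#'
#' @param props A [thermal_properties()] object.
#' @param mode `"paper_constant"` or `"computed"`.
#' @return Bulk heat diffusivity in m2 yr-1.
#' @export
bulk_heat_diffusivity <- function(props = thermal_properties(),
                                  mode = c("paper_constant", "computed")) {
  mode <- match.arg(mode)
  if (mode == "paper_constant") return(33.4273)
  phi <- props$porosity
  lambda <- props$lambda_w^phi * props$lambda_s^(1 - phi)
  heat_cap <- phi * props$rho_w * props$C_w + (1 - phi) * props$rho_s * props$C_s
  lambda / heat_cap * SECONDS_PER_YEAR
}
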