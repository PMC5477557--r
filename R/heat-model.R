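#' Bottom-water temperature forcing
#'
#' `forcing(t) = mean + amplitude * sin(2*pi*(t - phase)/period) +
#' warming_rate * min(t, warming_duration)`.  Defaults describe the seasonal
#' cycle at the study region: mean 1.25 degC with a 3.25 degC amplitude
#' (seasonal range about -2 to 4.5 degC) and the phase set so the maximum
#' falls in early September.
#'
#' @param mean Mean bottom-water temperature, degC.
#' @param amplitude Seasonal amplitude, degC (>= 0).
#' @param period Period in years.
#' @param phase Phase offset in years (time of the upward zero crossing).
#' @param warming_rate Linear warming rate, degC yr-1.
#' @param warming_duration Years over which the warming ramp applies.
#' @return Object of class `"temperature_forcing"`; callable via
#'   `forcing_values()`.
#' @export
temperature_forcing <- function(mean = 1.25, amplitude = 3.25, period = 1,
                                phase = 0.43, warming_rate = 0,
                                warming_duration = Inf) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (period <= 0) stop("period must be positive")
  structure(list(mean = mean, amplitude = amplitude, period = period,
                 phase = phase, warming_rate = warming_rate,
                 warming_duration = warming_duration),
            class = "temperature_forcing")
}

#' Evaluate a temperature forcing at given times
#' @param forcing A [temperature_forcing()].
#' @param t Times in years.
#' @return Temperatures in degC.
#' @export
forcing_values <- function(forcing, t) {
  forcing$mean +
    forcing$amplitude * sin(2 * pi * (t - forcing$phase) / forcing$period) +
    forcing$warming_rate * pmin(t, forcing$warming_duration)
}

#' Propagate bottom-water temperature into the sediment column
#'
#' Crank-Nicolson heat conduction with the forcing imposed at the seafloor
#' interface and a fixed geothermal gradient at the base.  The initial
#' condition is the steady geotherm `forcing$mean + gradient * z`.
#'
#' @param forcing A [temperature_forcing()].
#' @param column A [sediment_column()]; must be uniform.
#' @param kappa Bulk heat diffusivity, m2 yr-1 (> 0); default
#'   [bulk_heat_diffusivity()].
#' @param duration Simulated years.
#' @param dt Time step in years (default 0.05).
#' @param geotherm_gradient Basal gradient, degC m-1 (default 0.044).
#' @param snap_every Record a snapshot every `snap_every` steps.
#' @return Object of class `"temperature_field"`: `times`, matrix `T`
#'   (snapshots x cells), `column`, `forcing`, `kappa`,
#'   `geotherm_gradient`.
#' @export
propagate_temperature <- function(forcing, column = sediment_column(60, 0.025),
                                  kappa = bulk_heat_diffusivity(),
                                  duration = 12, dt = 0.05,
                                  geotherm_gradient = 0.044,
                                  snap_every = 1L) {
  if (kappa <= 0) stop("kappa must be positive")
  if (length(unique(column$dx)) != 1) stop("heat model expects a uniform grid")
  n_steps <- as.integer(round(duration / dt))
  tvals <- forcing_values(forcing, seq(0, n_steps) * dt)
  T0 <- forcing$mean + geotherm_gradient * column$cell_centres
  run <- cn_run_heat(T0, column$dx[1], dt, kappa, tvals, geotherm_gradient,
                     as.integer(snap_every))
  structure(list(times = run$time, T = run$T, column = column,
                 forcing = forcing, kappa = kappa,
                 geotherm_gradient = geotherm_gradient, dt = dt),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("temperature field: %d snapshots over %.3g yr on a %.3g-m column (kappa %.4g m2 yr-1)\n",
              length(x$times), max(x$times), x$column$length, x$kappa))
  invisible(x)
}

#' Assess gas-hydrate stability of a temperature field
#'
#' Flags, per snapshot, the cells whose temperature exceeds the hydrate
#' equilibrium temperature `T_eq(z)` of the phase boundary, and aggregates
#' destabilization extremes.  Monthly exceedance counts are computed over the
#' final simulated year.
#'
#' @param field A `"temperature_field"`.
#' @param boundary A [phase_boundary_profile()].
#' @return Object of class `"stability_report"`: per-snapshot maximum
#'   destabilized depth (`max_depth_t`, `NA` when fully stable), overall
#'   `max_destabilization_depth`, `months_exceeding` (per cell, final year),
#'   `time_to_full_column_destabilization` (`NA` if never), and the logical
#'   matrix `unstable`.
#' @export
assess_stability <- function(field, boundary) {
  stopifnot(inherits(field, "temperature_field"),
            inherits(boundary, "hydrate_phase_boundary"))
  if (boundary$anchor_depth < max(field$column$cell_centres) - 1e-9)
    stop("geometry error: phase boundary anchored shallower than the column base")
  Teq <- boundary$T_eq(field$column$cell_centres)
  unstable <- sweep(field$T, 2, Teq, `>`)
  zc <- field$column$cell_centres
  max_depth_t <- apply(unstable, 1, function(u) if (any(u)) max(zc[u]) else NA_real_)
  full <- apply(unstable, 1, all)
  t_full <- if (any(full)) field$times[which(full)[1]] else NA_real_
  last_year <- field$times > max(field$times) - 1
  month_bin <- floor((field$times[last_year] %% 1) * 12)
  months_exceeding <- apply(unstable[last_year, , drop = FALSE], 2, function(u)
    length(unique(month_bin[u])))
  structure(list(max_depth_t = max_depth_t,
                 max_destabilization_depth =
                   if (all(is.na(max_depth_t))) 0 else max(max_depth_t, na.rm = TRUE),
                 months_exceeding = months_exceeding,
                 time_to_full_column_destabilization = t_full,
                 unstable = unstable, times = field$times,
                 depth = zc, boundary = boundary),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("gas-hydrate stability report\n")
  cat(sprintf("  maximum destabilization depth: %.2f mbsf\n",
              x$max_destabilization_depth))
  if (is.na(x$time_to_full_column_destabilization))
    cat("  full column never destabilized\n")
  else
    cat(sprintf("  full column destabilized at t = %.2f yr\n",
                x$time_to_full_column_destabilization))
  invisible(x)
}

#' @export
plot.stability_report <- function(x, ...) {
  plot(x$times, ifelse(is.na(x$max_depth_t), 0, x$max_depth_t), type = "l",
       xlab = "time (yr)", ylab = "max destabilized depth (mbsf)",
       ylim = rev(range(c(0, x$max_depth_t), na.rm = TRUE)), ...)
  invisible(x)
}

#' Run a hydrate-stability scenario of the heat model
#'
#' `"seasonal"`: sinusoidal forcing only.  `"fast"`: an additional
#' 0.033 degC yr-1 warming for 30 years (about one degree in total).
#' `"slow"`: 0.005 degC yr-1 for 300 years (1.5 degrees in total).
#'
#' @param kind `"seasonal"`, `"fast"` or `"slow"`.
#' @param forcing Base [temperature_forcing()] (warming fields are
#'   overridden by `kind`).
#' @param boundary A [phase_boundary_profile()].
#' @param column A [sediment_column()].
#' @param kappa Bulk heat diffusivity, m2 yr-1.
#' @param geotherm_gradient Basal gradient, degC m-1.
#' @param duration Override of the simulated years (defaults per kind:
#'   12 seasonal, 30 fast, 300 slow).
#' @param snap_every Snapshot stride in steps (default chosen per kind).
#' @return A `"stability_report"`, with the `"temperature_field"` attached
#'   as `$field`.
#' @export
run_warming_scenario <- function(kind = c("seasonal", "fast", "slow"),
                                 forcing = temperature_forcing(),
                                 boundary = phase_boundary_profile(),
                                 column = sediment_column(60, 0.025),
                                 kappa = bulk_heat_diffusivity(),
                                 geotherm_gradient = 0.044,
                                 duration = NULL, snap_every = NULL) {
  kind <- match.arg(kind)
  pars <- switch(kind,
                 seasonal = list(rate = 0,     dur = Inf, years = 12, snap = 1L),
                 fast     = list(rate = 0.033, dur = 30,  years = 30, snap = 1L),
                 slow     = list(rate = 0.005, dur = 300, years = 300, snap = 4L))
  forcing$warming_rate <- pars$rate
  forcing$warming_duration <- pars$dur
  if (is.null(duration)) duration <- pars$years
  if (is.null(snap_every)) snap_every <- pars$snap
  field <- propagate_temperature(forcing, column, kappa, duration,
                                 geotherm_gradient = geotherm_gradient,
                                 snap_every = snap_every)
  rep <- assess_stability(field, boundary)
  rep$kind <- kind
  rep$field <- field
  rep
}
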