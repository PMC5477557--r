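#' Detect the kink of a non-steady-state sulfate profile
#'
#' Change-point detection by exhaustive two-segment piecewise-linear fitting:
#' the breakpoint minimizing the total residual sum of squares is selected,
#' and the shallow segment must be near-flat (|slope| below
#' `flat_slope_max`), the diagnostic of a relic seawater-like upper segment
#' over a steep decline.
#'
#' @param depth,conc Depth (mbsf) and sulfate concentration (mol m-3),
#'   sorted by depth, at least 6 points.
#' @param flat_slope_max Maximum |slope| of the shallow segment,
#'   mol m-3 m-1.
#' @param min_steepening Required ratio of deep to shallow |slope|.
#' @param zero_tol Concentrations below this level mark the exhausted tail
#'   beneath the SMTZ, which is excluded from the segment fits (keeping one
#'   point past the crossing).
#' @return List with `depth` (kink depth, m), `index` (into the full input),
#'   `slope_shallow`, `slope_deep`.
#' @export
detect_kink <- function(depth, conc, flat_slope_max = 8, min_steepening = 2.5,
                        zero_tol = 0.4) {
  stopifnot(length(depth) == length(conc))
  # drop the exhausted tail below the SMTZ; the kink lives above it
  n_keep <- length(conc)
  if (any(conc < zero_tol)) n_keep <- min(which(conc < zero_tol))
  n_keep <- min(n_keep + 1, length(conc))
  depth <- depth[seq_len(n_keep)]; conc <- conc[seq_len(n_keep)]
  n <- length(depth)
  if (n < 6) stop("shape error: need at least 6 points to detect a kink")
  best <- NULL; best_sse <- Inf
  for (k in 3:(n - 3)) {
    i1 <- 1:k; i2 <- k:n
    f1 <- stats::lm.fit(cbind(1, depth[i1]), conc[i1])
    f2 <- stats::lm.fit(cbind(1, depth[i2]), conc[i2])
    sse <- sum(f1$residuals^2) + sum(f2$residuals^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- list(depth = depth[k], index = k,
                   slope_shallow = f1$coefficients[2],
                   slope_deep = f2$coefficients[2])
    }
  }
  if (abs(best$slope_shallow) > flat_slope_max ||
      abs(best$slope_deep) < min_steepening * abs(best$slope_shallow))
    stop("shape error: no kink detected (shallow segment not flat or no steepening)")
  best
}

#' Date the onset of a methane pulse from an observed sulfate profile
#'
#' The inverse problem of the reduced diffusion-AOM model.  For each
#' tortuosity in the bracket: (1) the kink separating the relic shallow
#' segment from the steep decline is located (a shape check and the anchor
#' of the weak-supply first guess); (2) the weak bottom-methane supply and
#' the elapsed time since the pulse are fitted jointly -- for each trial
#' supply the weak steady state is spun up, the pulse simulated forward,
#' and the trajectory scanned for the time minimizing the depth-weighted
#' RMS misfit between simulated and observed sulfate over the whole
#' profile; the supply minimizing that profiled misfit is selected.  The
#' shallow segment keeps evolving after the pulse, so fitting the supply
#' against it alone (as if it were an unmodified relic) would bias the
#' onset low.  The per-tortuosity estimates and their envelope form the
#' onset interval.
#'
#' The misfit is monitored along a single forward trajectory (every
#' `scan_resolution` years) with an early stop once it has risen well past
#' its minimum; this is equivalent to, and cheaper than, a line search that
#' re-simulates from zero for every trial time, and it also exposes
#' non-unimodal misfit curves, which trigger a warning.
#'
#' @param observed Data frame with `depth_mbsf` and `concentration`
#'   (sulfate, mol m-3), e.g. one species of a profile read by
#'   [read_profile_csv()], or a `"porewater_profile"` (its sulfate rows are
#'   used).
#' @param config A [reduced_model_config()].
#' @param thetas Tortuosity bracket (default from the config).
#' @param hydrate_depth Optional depth (mbsf) of the shallowest observed gas
#'   hydrate or gas microfracture; used as the gas-front emplacement depth of
#'   the pulse (dissolved methane is at its solubility ceiling where free gas
#'   or hydrate is present).  Falls back to `config$gas_front_depth`, then to
#'   the spun-up SMTZ depth.
#' @param max_duration Upper bound of the time scan, years.
#' @param scan_resolution Misfit sampling interval along the trajectory,
#'   years.
#' @param site_id Label carried into the result.
#' @return Object of class `"onset_fit"`.
#' @export
fit_onset <- function(observed, config = reduced_model_config(),
                      thetas = NULL, hydrate_depth = NULL,
                      max_duration = 20000, scan_resolution = 0.5,
                      site_id = "site") {
  if (inherits(observed, "porewater_profile") && "species" %in% names(observed)) {
    observed <- as.data.frame(observed)
    observed <- observed[observed$species == "SO4",
                         c("depth_mbsf", "concentration")]
  }
  observed <- as.data.frame(observed)
  stopifnot(all(c("depth_mbsf", "concentration") %in% names(observed)))
  observed <- observed[order(observed$depth_mbsf), ]
  depth <- observed$depth_mbsf; conc <- observed$concentration
  if (is.null(thetas)) thetas <- config$tortuosities
  kink <- detect_kink(depth, conc)
  shallow <- observed[seq_len(kink$index), ]
  deep_idx <- which(depth >= kink$depth)
  # depth weighting: trapezoid quadrature weights so irregular sampling does
  # not bias the RMS
  dzf <- diff(depth)
  wts_full <- c(dzf / 2, 0) + c(0, dzf / 2)
  fits <- list()
  for (th in thetas) {
    col <- sediment_column(config$length, config$dx, config$porosity, th)
    zc <- col$cell_centres
    # interpolation stencils mapping cell centres to observation depths
    i0 <- findInterval(depth, zc)
    i0 <- pmin(pmax(i0, 1L), col$n_cells - 1L)
    w <- (depth - zc[i0]) / (zc[i0 + 1] - zc[i0])
    w <- pmin(pmax(w, 0), 1)
    Ds <- .reduced_Ds(config, th)
    misfit_every <- max(1L, as.integer(round(scan_resolution / config$dt)))
    warm <- NULL
    pulse_init <- function(c_weak) {
      cfg_w <- config; cfg_w$ch4_bottom_weak <- c_weak
      init <- spin_up_initial_state(cfg_w, th, settle_years = 0,
                                    warm_start = warm)
      warm <<- list(so4 = init$so4, ch4 = init$ch4)
      zg <- if (!is.null(hydrate_depth)) hydrate_depth
            else if (!is.null(config$gas_front_depth)) config$gas_front_depth
            else smtz_depth(zc, init$so4)
      ch4 <- init$ch4
      sel <- zc >= zg
      ch4[sel] <- pmax(ch4[sel], config$ch4_bottom_strong)
      list(init = init, ch4 = ch4, zg = zg)
    }
    run_pulse <- function(pi, n_steps) {
      cn_run_reduced(pi$init$so4, pi$ch4, config$dx, config$dt,
                     Ds$so4, Ds$ch4, config$sulfate_top, 0,
                     config$ch4_bottom_strong,
                     config$kinetics$k_max, config$kinetics$K_SO4,
                     config$kinetics$K_CH4, n_steps,
                     obs_i0 = i0 - 1L, obs_w = w,
                     obs_val = conc, obs_wt = wts_full,
                     misfit_every = misfit_every,
                     stop_factor = 2, stop_overshoot = 1.5,
                     stop_window = as.integer(round(20 / config$dt)),
                     snap_steps = integer(0))
    }
    # flux-balance first guess for the weak supply from the shallow segment
    sl <- stats::lm.fit(cbind(1, shallow$depth_mbsf),
                        shallow$concentration)$coefficients[2]
    z0 <- config$sulfate_top / max(abs(sl), config$sulfate_top / (2 * config$length))
    z0 <- min(z0, 0.95 * config$length)
    c_guess <- config$sulfate_top * Ds$so4 * (config$length - z0) / (Ds$ch4 * z0)
    # Joint least-squares fit of (weak supply, elapsed time) by profile
    # likelihood: for each trial weak supply the forward trajectory is
    # scanned for the time minimizing the depth-weighted RMS misfit over the
    # whole profile, and the weak supply minimizing that profiled misfit is
    # selected.  (The shallow segment keeps evolving after the pulse, so a
    # relic-only fit of the weak supply would bias the onset estimate.)
    scan_fn <- function(cb) {
      pic <- pulse_init(cb)
      list(run = run_pulse(pic, as.integer(round(max_duration / config$dt))),
           pic = pic)
    }
    opt <- optimize(function(cb) scan_fn(cb)$run$best_misfit,
                    interval = c(c_guess / 5, c_guess * 5),
                    tol = max(0.03, c_guess / 50))
    best <- scan_fn(opt$minimum)
    run <- best$run
    init <- best$pic$init; zg <- best$pic$zg
    mt <- run$misfit_time; mv <- run$misfit
    if (which.min(mv) == length(mv))
      warning("misfit still decreasing at max_duration; onset estimate is a lower bound")
    if (.n_local_minima(mv) > 1)
      warning("misfit curve is not unimodal; inspect $misfit_curve")
    # refit the profile at the estimated onset for predictions/residuals
    traj <- simulate_pulse(init, duration = run$best_time,
                           snapshot_times = run$best_time,
                           gas_front_depth = zg)
    fits[[as.character(th)]] <- list(
      theta = th, onset = run$best_time, misfit = run$best_misfit,
      misfit_curve = data.frame(time = mt, misfit = mv),
      initial = init, gas_front_depth = zg,
      fitted_so4 = traj$final$so4, fitted_ch4 = traj$final$ch4)
  }
  onsets <- vapply(fits, `[[`, numeric(1), "onset")
  out <- list(site_id = site_id,
              onset_years_by_tortuosity = onsets,
              onset_interval = range(onsets),
              fitted_ch4_bottom = config$ch4_bottom_strong,
              misfit = min(vapply(fits, `[[`, numeric(1), "misfit")),
              kink = kink, fits = fits, observed = observed,
              deep_idx = deep_idx, config = config,
              saturation_depth = saturation_depth(
                fits[[1]]$initial$column$cell_centres, fits[[1]]$fitted_ch4,
                config$ch4_bottom_strong))
  class(out) <- "onset_fit"
  out
}

# count local minima with prominence above rel_tol of the curve's range
.n_local_minima <- function(v, rel_tol = 0.05) {
  n <- length(v); scale <- max(v) - min(v)
  if (n < 3 || scale <= 0) return(1L)
  idx <- which(diff(sign(diff(v))) > 0) + 1
  count <- 0L
  for (i in idx) {
    rise <- min(max(v[1:i]) - v[i], max(v[i:n]) - v[i])
    if (rise > rel_tol * scale) count <- count + 1L
  }
  max(1L, count)
}

#' @export
print.onset_fit <- function(x, ...) {
  cat(sprintf("Methane-pulse onset fit for %s\n", x$site_id))
  for (nm in names(x$onset_years_by_tortuosity))
    cat(sprintf("  tortuosity %s: onset %.4g yr before present\n",
                nm, x$onset_years_by_tortuosity[[nm]]))
  cat(sprintf("  onset interval: %.4g - %.4g yr\n",
              x$onset_interval[1], x$onset_interval[2]))
  invisible(x)
}

#' @export
summary.onset_fit <- function(object, ...) {
  cat(sprintf("Methane-pulse onset fit for %s\n", object$site_id))
  cat(sprintf("  kink at %.2f mbsf (shallow slope %.3g, deep slope %.3g mol m-3 m-1)\n",
              object$kink$depth, object$kink$slope_shallow, object$kink$slope_deep))
  for (f in object$fits)
    cat(sprintf("  theta %.2f: onset %.4g yr, weighted RMS misfit %.3g mol m-3, weak CH4 bottom %.3g mol m-3, gas front %.2f mbsf\n",
                f$theta, f$onset, f$misfit, f$initial$ch4_bottom, f$gas_front_depth))
  cat(sprintf("  reservoir (strong) CH4: %.3g mol m-3; modelled saturation depth %.2f mbsf\n",
              object$fitted_ch4_bottom, object$saturation_depth))
  invisible(object)
}

#' @export
coef.onset_fit <- function(object, ...) {
  c(object$onset_years_by_tortuosity,
    onset_min = object$onset_interval[1],
    onset_max = object$onset_interval[2])
}

#' Fitted porewater profiles of an onset fit
#'
#' @param object An `"onset_fit"`.
#' @param theta Which tortuosity's fit to return (default: smallest misfit).
#' @param at Depths at which to interpolate; default the observation depths.
#' @param ... Unused.
#' @return Data frame with `depth_mbsf`, `so4`, `ch4`.
#' @export
predict.onset_fit <- function(object, theta = NULL, at = NULL, ...) {
  f <- .pick_fit(object, theta)
  zc <- f$initial$column$cell_centres
  if (is.null(at)) at <- object$observed$depth_mbsf
  data.frame(depth_mbsf = at,
             so4 = approx(zc, f$fitted_so4, xout = at, rule = 2)$y,
             ch4 = approx(zc, f$fitted_ch4, xout = at, rule = 2)$y)
}

#' @export
residuals.onset_fit <- function(object, theta = NULL, ...) {
  f <- .pick_fit(object, theta)
  idx <- object$deep_idx
  obs <- object$observed[idx, ]
  sim <- approx(f$initial$column$cell_centres, f$fitted_so4,
                xout = obs$depth_mbsf, rule = 2)$y
  structure(obs$concentration - sim, names = format(obs$depth_mbsf))
}

.pick_fit <- function(object, theta) {
  if (is.null(theta)) {
    mis <- vapply(object$fits, `[[`, numeric(1), "misfit")
    object$fits[[which.min(mis)]]
  } else object$fits[[as.character(theta)]]
}

#' @export
plot.onset_fit <- function(x, theta = NULL, max_depth = NULL, ...) {
  f <- .pick_fit(x, theta)
  obs <- x$observed
  if (is.null(max_depth)) max_depth <- max(obs$depth_mbsf) * 1.2
  zc <- f$initial$column$cell_centres
  sel <- zc <= max_depth
  plot(obs$concentration, obs$depth_mbsf, ylim = c(max_depth, 0),
       xlab = "sulfate (mol m-3)", ylab = "depth (mbsf)",
       main = sprintf("%s: onset %.4g yr (theta %.2f)", x$site_id, f$onset, f$theta), ...)
  graphics::lines(f$initial$so4[sel], zc[sel], lty = 2)
  graphics::lines(f$fitted_so4[sel], zc[sel])
  graphics::abline(h = x$kink$depth, col = "grey")
  graphics::legend("bottomright", legend = c("observed", "initial", "fitted"),
                   lty = c(NA, 2, 1), pch = c(1, NA, NA), bty = "n")
  invisible(x)
}

#' Simulate noisy replicate profiles from a fitted onset model
#'
#' Parametric-bootstrap style: the fitted sulfate profile is resampled at the
#' observation depths with Gaussian noise at the residual standard deviation.
#'
#' @param object An `"onset_fit"`.
#' @param nsim Number of replicates.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return List of data frames (`depth_mbsf`, `concentration`).
#' @export
simulate.onset_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- .pick_fit(object, NULL)
  noise_sd <- sd(residuals(object))
  base <- predict(object)
  lapply(seq_len(nsim), function(i)
    data.frame(depth_mbsf = base$depth_mbsf,
               concentration = pmax(base$so4 + rnorm(nrow(base), 0, noise_sd), 0)))
}

#' Alias for [fit_onset()] matching the module operation name
#' @inheritParams fit_onset
#' @param ... Passed to [fit_onset()].
#' @export
estimate_onset_time <- function(observed, config = reduced_model_config(), ...) {
  fit_onset(observed, config, ...)
}
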