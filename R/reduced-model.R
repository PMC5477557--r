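#' Dual-Monod AOM rate
#'
#' Rate of anaerobic oxidation of methane,
#' `R = k_max * so4/(K_SO4 + so4) * ch4/(K_CH4 + ch4)`, consuming sulfate and
#' methane 1:1.
#'
#' @param so4,ch4 Concentrations in mol m-3 (vectors allowed, non-negative).
#' @param kinetics List with `k_max` (mol m-3 yr-1), `K_SO4`, `K_CH4`
#'   (mol m-3); see [aom_kinetics()].
#' @return Rate in mol m-3 yr-1.
#' @examples
#' aom_rate(0.5, 5) # both at half saturation: k_max / 4
#' @export
aom_rate <- function(so4, ch4, kinetics = aom_kinetics()) {
  if (any(so4 < 0) || any(ch4 < 0)) stop("concentrations must be non-negative")
  kinetics$k_max * so4 / (kinetics$K_SO4 + so4) * ch4 / (kinetics$K_CH4 + ch4)
}

#' AOM kinetic constants
#'
#' Defaults: maximum rate 2 mol m-3 yr-1 (from fitting the sulfate profile;
#' it shapes the profile near the SMTZ but not the migration rate), half
#' saturation 0.5 mol m-3 for sulfate and 5 mol m-3 for methane.
#'
#' @param k_max,K_SO4,K_CH4 Strictly positive constants.
#' @return List of class `"aom_kinetics"`.
#' @export
aom_kinetics <- function(k_max = 2, K_SO4 = 0.5, K_CH4 = 5) {
  if (any(c(k_max, K_SO4, K_CH4) <= 0)) stop("kinetic constants must be positive")
  structure(list(k_max = k_max, K_SO4 = K_SO4, K_CH4 = K_CH4),
            class = "aom_kinetics")
}

#' Configuration of the reduced sulfate-methane model
#'
#' The pulse-dating model: a 60-m purely diffusive column (no burial or
#' compaction advection) in which AOM is the only reaction.  Sulfate has a
#' fixed seawater value at the top and a no-flux bottom; methane is held at 0
#' at the top and at a fixed reservoir concentration at the bottom.
#'
#' @param length,dx Column geometry in m (defaults 60, 0.025).
#' @param porosity Porosity (0.7).
#' @param dt Time step in years (0.01; 0.025 is used for multi-millennial
#'   runs).
#' @param tortuosities Tortuosity bracket used for onset dating (1.5, 2.2).
#' @param T_bottom_water Bottom-water temperature in degC used for the
#'   diffusivities (0.56).
#' @param sulfate_top Seawater sulfate at the seafloor, mol m-3.
#' @param ch4_bottom_weak,ch4_bottom_strong Bottom-boundary methane before
#'   and after the pulse, mol m-3.  The strong value defaults to the
#'   dissolved-methane ceiling at hydrate equilibrium (64 mol m-3).
#' @param gas_front_depth Depth (mbsf) to which the methane pulse emplaces
#'   reservoir-level dissolved methane at onset, representing rapid free-gas
#'   ascent to the base of the sulfate zone; `NULL` means boundary-only
#'   forcing at the column base.
#' @param kinetics An [aom_kinetics()] object.
#' @return List of class `"reduced_model_config"`.
#' @export
reduced_model_config <- function(length = 60, dx = 0.025, porosity = 0.7,
                                 dt = 0.01, tortuosities = c(1.5, 2.2),
                                 T_bottom_water = 0.56, sulfate_top = 28,
                                 ch4_bottom_weak = 15,
                                 ch4_bottom_strong = 64,
                                 gas_front_depth = NULL,
                                 kinetics = aom_kinetics()) {
  if (ch4_bottom_weak < 0 || ch4_bottom_strong <= ch4_bottom_weak)
    stop("require ch4_bottom_strong > ch4_bottom_weak >= 0")
  if (dt <= 0) stop("dt must be positive")
  structure(list(length = length, dx = dx, porosity = porosity, dt = dt,
                 tortuosities = tortuosities,
                 T_bottom_water = T_bottom_water, sulfate_top = sulfate_top,
                 ch4_bottom_weak = ch4_bottom_weak,
                 ch4_bottom_strong = ch4_bottom_strong,
                 gas_front_depth = gas_front_depth, kinetics = kinetics),
            class = "reduced_model_config")
}

# porous diffusivities at the configured bottom-water temperature
.reduced_Ds <- function(config, theta) {
  list(so4 = porous_media_diffusivity(
         free_solution_diffusivity("sulfate", config$T_bottom_water), theta),
       ch4 = porous_media_diffusivity(
         free_solution_diffusivity("methane", config$T_bottom_water), theta))
}

# Steady state of the coupled sulfate-methane-AOM column: damped Newton on
# the full coupled nonlinear system with interleaved unknowns
# (S_1, M_1, S_2, M_2, ...), whose Jacobian is banded with bandwidth 2
# (diffusion couples neighbouring cells, AOM couples S_i and M_i).
.reduced_steady <- function(config, theta, ch4_bottom, tol = 1e-11,
                            max_iter = 80, s_init = NULL, m_init = NULL,
                            retry = TRUE) {
  n <- round(config$length / config$dx)
  dx <- config$dx
  Ds <- .reduced_Ds(config, theta)
  kin <- config$kinetics
  s_top <- config$sulfate_top
  rS <- Ds$so4 / dx^2; rM <- Ds$ch4 / dx^2
  # analytic flux-balance guess for the SMTZ depth
  rr <- max(ch4_bottom * Ds$ch4 / (s_top * Ds$so4), 1e-6)
  z0 <- config$length / (1 + rr)
  zc <- (seq_len(n) - 0.5) * dx
  s <- if (!is.null(s_init)) s_init else pmax(s_top * (1 - zc / z0), 0)
  m <- if (!is.null(m_init)) m_init else
    pmax(ch4_bottom * (zc - z0) / (config$length - z0), 0)

  lap <- function(x, r, top, bottom) {
    # D/dx^2 second difference with ghost cells (NULL = no flux)
    xm <- c(if (is.null(top)) x[1] else 2 * top - x[1], x[-n])
    xp <- c(x[-1], if (is.null(bottom)) x[n] else 2 * bottom - x[n])
    r * (xm - 2 * x + xp)
  }
  resid <- function(s, m) {
    sp <- pmax(s, 0); mp <- pmax(m, 0)
    R <- kin$k_max * sp / (kin$K_SO4 + sp) * mp / (kin$K_CH4 + mp)
    list(fS = lap(s, rS, s_top, NULL) - R,
         fM = lap(m, rM, 0, ch4_bottom) - R,
         R = R, sp = sp, mp = mp)
  }
  fr <- resid(s, m)
  fnorm <- max(abs(c(fr$fS, fr$fM)))
  for (it in seq_len(max_iter)) {
    if (fnorm < tol * max(1, kin$k_max)) break
    sp <- fr$sp; mp <- fr$mp
    gS <- kin$k_max * kin$K_SO4 / (kin$K_SO4 + sp)^2 * mp / (kin$K_CH4 + mp) * (s > 0)
    gM <- kin$k_max * sp / (kin$K_SO4 + sp) * kin$K_CH4 / (kin$K_CH4 + mp)^2 * (m > 0)
    # interleaved banded Jacobian: rows 2i-1 = S-cell i, rows 2i = M-cell i
    N <- 2L * n
    diags <- matrix(0, 5, N)
    iS <- seq(1, N, by = 2); iM <- seq(2, N, by = 2)
    dS <- rep(-2 * rS, n); dM <- rep(-2 * rM, n)
    dS[1] <- -3 * rS; dM[1] <- -3 * rM       # Dirichlet tops
    dS[n] <- -1 * rS                          # no-flux bottom (S)
    dM[n] <- -3 * rM                          # Dirichlet bottom (M)
    diags[3, iS] <- dS - gS
    diags[3, iM] <- dM - gM
    diags[4, iS] <- -gM                       # dfS/dM_i (offset +1)
    diags[2, iM] <- -gS                       # dfM/dS_i (offset -1)
    diags[1, iS[-1]] <- rS                    # dfS_i/dS_{i-1} (offset -2)
    diags[5, iS[-n]] <- rS                    # dfS_i/dS_{i+1} (offset +2)
    diags[1, iM[-1]] <- rM
    diags[5, iM[-n]] <- rM
    rhs <- numeric(N); rhs[iS] <- -fr$fS; rhs[iM] <- -fr$fM
    step <- band2_solve(diags, rhs)
    lam <- 1
    repeat {
      s_new <- s + lam * step[iS]
      m_new <- m + lam * step[iM]
      fr_new <- resid(s_new, m_new)
      fn_new <- max(abs(c(fr_new$fS, fr_new$fM)))
      if (fn_new < fnorm || lam < 1e-4) break
      lam <- lam / 2
    }
    s <- s_new; m <- m_new; fr <- fr_new; fnorm <- fn_new
  }
  if (fnorm >= 1e-6 * max(1, kin$k_max)) {
    if (retry) {
      # precondition with a transient relaxation from the analytic guess,
      # then retry Newton; sharp fronts at strong supplies need this
      Ds2 <- .reduced_Ds(config, theta)
      pre <- cn_run_reduced(pmax(s_top * (1 - zc / z0), 0),
                            pmax(ch4_bottom * (zc - z0) / (config$length - z0), 0),
                            dx, 0.5, Ds2$so4, Ds2$ch4, s_top, 0, ch4_bottom,
                            kin$k_max, kin$K_SO4, kin$K_CH4, 2000L,
                            obs_i0 = integer(0), obs_w = numeric(0),
                            obs_val = numeric(0), obs_wt = numeric(0),
                            misfit_every = 0L, stop_factor = 0,
                            stop_overshoot = 0, stop_window = 0L,
                            snap_steps = integer(0))
      return(.reduced_steady(config, theta, ch4_bottom, tol, max_iter,
                             s_init = pre$so4, m_init = pre$ch4,
                             retry = FALSE))
    }
    stop("spin-up failed to converge; check the weak methane boundary value")
  }
  list(so4 = pmax(s, 0), ch4 = pmax(m, 0), n = n)
}

#' Spin up the weak-flux initial state of the reduced model
#'
#' Computes the steady state of the coupled diffusion-AOM column under a weak
#' bottom methane supply -- the pre-pulse initial condition.  When a shallow
#' target sulfate segment is supplied, the weak methane boundary value is
#' adjusted until the steady profile matches the segment in least squares.
#'
#' @param config A [reduced_model_config()].
#' @param theta Tortuosity.
#' @param target_shallow Optional data frame with `depth_mbsf` and
#'   `concentration` (sulfate, mol m-3) for the shallow (pre-kink) segment.
#' @param warm_start Optional list with `so4`/`ch4` fields used as the
#'   Newton starting point (e.g. a previous nearby steady state).
#' @param settle_years After the Newton solve, the transient scheme is run
#'   for this long so the state returned is the fixed point of the
#'   operator-split stepper itself (the two differ by a small splitting
#'   bias near the reaction front).
#' @param verify If `TRUE`, integrates the transient model for one further
#'   century and reports the relative drift (must be < 1e-8 for a converged
#'   steady state).
#' @return Object of class `"reduced_state"`: fields `so4`, `ch4`,
#'   `column`, `config`, `theta`, `ch4_bottom`, `time`, and `drift`
#'   (`NA` unless verified).
#' @export
spin_up_initial_state <- function(config, theta = 1.5, target_shallow = NULL,
                                  settle_years = 800, verify = FALSE,
                                  warm_start = NULL) {
  c_weak <- config$ch4_bottom_weak
  col <- sediment_column(config$length, config$dx, config$porosity, theta)
  if (!is.null(target_shallow)) {
    stopifnot(all(c("depth_mbsf", "concentration") %in% names(target_shallow)))
    obj <- function(cb) {
      st <- .reduced_steady(config, theta, cb)
      sim <- approx(col$cell_centres, st$so4, xout = target_shallow$depth_mbsf,
                    rule = 2)$y
      sum((sim - target_shallow$concentration)^2)
    }
    # analytic flux-balance guess from the shallow sulfate gradient brackets
    # the search
    sl <- stats::lm.fit(cbind(1, target_shallow$depth_mbsf),
                        target_shallow$concentration)$coefficients[2]
    Ds <- .reduced_Ds(config, theta)
    z0 <- config$sulfate_top / max(abs(sl), config$sulfate_top / (2 * config$length))
    z0 <- min(z0, 0.95 * config$length)
    c_guess <- config$sulfate_top * Ds$so4 * (config$length - z0) /
      (Ds$ch4 * z0)
    c_weak <- optimize(obj, interval = c(c_guess / 5, c_guess * 5),
                       tol = max(0.02, c_guess / 200))$minimum
  }
  st <- .reduced_steady(config, theta, c_weak,
                        s_init = warm_start$so4, m_init = warm_start$ch4)
  so4 <- st$so4; ch4 <- st$ch4
  run_transient <- function(so4, ch4, years) {
    Ds <- .reduced_Ds(config, theta)
    cn_run_reduced(so4, ch4, config$dx, config$dt,
                   Ds$so4, Ds$ch4, config$sulfate_top, 0, c_weak,
                   config$kinetics$k_max, config$kinetics$K_SO4,
                   config$kinetics$K_CH4,
                   n_steps = as.integer(round(years / config$dt)),
                   obs_i0 = integer(0), obs_w = numeric(0),
                   obs_val = numeric(0), obs_wt = numeric(0),
                   misfit_every = 0L, stop_factor = 0,
                   stop_overshoot = 0, stop_window = 0L, snap_steps = integer(0))
  }
  if (settle_years > 0) {
    run <- run_transient(so4, ch4, settle_years)
    so4 <- run$so4; ch4 <- run$ch4
  }
  out <- structure(list(so4 = so4, ch4 = ch4, column = col,
                        config = config, theta = theta,
                        ch4_bottom = c_weak, time = 0, drift = NA_real_),
                   class = "reduced_state")
  if (verify) {
    run <- run_transient(so4, ch4, 100)
    out$drift <- max(abs(run$so4 - so4)) / max(abs(so4))
  }
  out
}

#' @export
print.reduced_state <- function(x, ...) {
  cat(sprintf("reduced-model state (theta = %.2f): t = %.3g yr, SMTZ at %.2f mbsf, CH4 bottom %.3g mol m-3\n",
              x$theta, x$time, smtz_depth(x$column$cell_centres, x$so4),
              x$ch4_bottom))
  invisible(x)
}

#' Depth of the sulfate-methane transition zone
#'
#' Shallowest depth at which sulfate falls below the 0.4 mol m-3 threshold
#' (linearly interpolated); `Inf` if sulfate never does.
#'
#' @param depth,so4 Depth (m) and sulfate (mol m-3) vectors.
#' @param threshold Crossing level, mol m-3.
#' @return Depth in m.
#' @export
smtz_depth <- function(depth, so4, threshold = 0.4) {
  .first_downcross(depth, so4, threshold)
}

.first_downcross <- function(depth, y, level) {
  below <- y < level
  if (!any(below)) return(Inf)
  i <- which(below)[1]
  if (i == 1) return(depth[1])
  depth[i - 1] + (level - y[i - 1]) * (depth[i] - depth[i - 1]) / (y[i] - y[i - 1])
}

#' Shallowest depth where methane reaches its solubility ceiling
#'
#' @param depth,ch4 Depth (m) and dissolved methane (mol m-3) vectors.
#' @param solubility Dissolved-methane ceiling, mol m-3 (> 0).
#' @return Depth in m (linear interpolation); `Inf` if never exceeded.
#' @export
saturation_depth <- function(depth, ch4, solubility = 64) {
  if (solubility <= 0) stop("solubility must be positive")
  above <- ch4 >= solubility
  if (!any(above)) return(Inf)
  i <- which(above)[1]
  if (i == 1) return(depth[1])
  depth[i - 1] + (solubility - ch4[i - 1]) * (depth[i] - depth[i - 1]) /
    (ch4[i] - ch4[i - 1])
}

#' Simulate the methane pulse from a spun-up initial state
#'
#' At `t = 0` the bottom methane boundary switches to the strong reservoir
#' value; when `gas_front_depth` is set (directly or via the config), the
#' dissolved methane field below that depth is raised to the reservoir value
#' as well, representing near-instantaneous free-gas ascent to the base of
#' the sulfate zone.  The coupled diffusion-AOM system is then integrated for
#' `duration` years.
#'
#' @param initial_state A `"reduced_state"` from [spin_up_initial_state()].
#' @param duration Simulated time in years.
#' @param snapshot_times Times (yr) at which to record profiles.
#' @param gas_front_depth Optional override of the config value, in mbsf.
#' @param ch4_bottom_strong Optional override of the reservoir concentration.
#' @return Object of class `"reduced_trajectory"`: `times`, matrices `so4`
#'   and `ch4` (snapshots x cells), `smtz` (per snapshot), final state, and
#'   AOM bookkeeping (`cum_aom`, `clip_count`).
#' @export
simulate_pulse <- function(initial_state, duration,
                           snapshot_times = NULL, gas_front_depth = NULL,
                           ch4_bottom_strong = NULL) {
  stopifnot(inherits(initial_state, "reduced_state"))
  config <- initial_state$config
  theta <- initial_state$theta
  col <- initial_state$column
  dt <- config$dt
  c_strong <- if (!is.null(ch4_bottom_strong)) ch4_bottom_strong else config$ch4_bottom_strong
  zg <- if (!is.null(gas_front_depth)) gas_front_depth else config$gas_front_depth
  ch4 <- initial_state$ch4
  if (!is.null(zg)) ch4[col$cell_centres >= zg] <- pmax(ch4[col$cell_centres >= zg], c_strong)
  n_steps <- max(0L, as.integer(round(duration / dt)))
  if (is.null(snapshot_times)) snapshot_times <- seq(0, duration, length.out = 11)[-1]
  snap_steps <- sort(unique(pmax(1L, as.integer(round(snapshot_times / dt)))))
  snap_steps <- snap_steps[snap_steps <= n_steps]
  if (n_steps == 0L) {
    out <- list(times = 0, so4 = matrix(initial_state$so4, nrow = 1),
                ch4 = matrix(ch4, nrow = 1),
                smtz = smtz_depth(col$cell_centres, initial_state$so4),
                final = initial_state, cum_aom = 0, clip_count = 0,
                column = col)
    class(out) <- "reduced_trajectory"
    return(out)
  }
  Ds <- .reduced_Ds(config, theta)
  run <- cn_run_reduced(initial_state$so4, ch4, config$dx, dt,
                        Ds$so4, Ds$ch4, config$sulfate_top, 0, c_strong,
                        config$kinetics$k_max, config$kinetics$K_SO4,
                        config$kinetics$K_CH4, n_steps,
                        obs_i0 = integer(0), obs_w = numeric(0),
                        obs_val = numeric(0), obs_wt = numeric(0),
                        misfit_every = 0L, stop_factor = 0, stop_overshoot = 0,
                        stop_window = 0L, snap_steps = snap_steps)
  k <- run$n_snaps_filled
  so4_m <- run$snap_so4[seq_len(k), , drop = FALSE]
  ch4_m <- run$snap_ch4[seq_len(k), , drop = FALSE]
  final <- initial_state
  final$so4 <- run$so4; final$ch4 <- run$ch4
  final$time <- n_steps * dt; final$ch4_bottom <- c_strong
  out <- list(times = snap_steps[seq_len(k)] * dt, so4 = so4_m, ch4 = ch4_m,
              smtz = apply(so4_m, 1, function(s) smtz_depth(col$cell_centres, s)),
              final = final, cum_aom = run$cum_aom,
              clip_count = run$clip_count, column = col)
  class(out) <- "reduced_trajectory"
  out
}

#' @export
print.reduced_trajectory <- function(x, ...) {
  cat(sprintf("reduced-model trajectory: %d snapshots over %.3g yr; SMTZ %.2f -> %.2f mbsf\n",
              length(x$times), max(x$times), x$smtz[1], x$smtz[length(x$smtz)]))
  invisible(x)
}
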