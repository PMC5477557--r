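#' Specification of a synthetic porewater dataset with known truth
#'
#' Describes the forward simulation and sampling used to emulate rhizon-type
#' porewater profiles from a seep with a dated methane pulse: a weak-supply
#' steady state, pulse emplacement at `gas_front_depth`, `true_onset` years
#' of evolution, sampling every 0.1 m over the upper 3 m, and additive
#' Gaussian measurement noise (sulfate default 0.3 mol m-3, about 1% of the
#' seawater value).
#'
#' @param true_onset Years since the pulse (the quantity the estimator must
#'   recover).
#' @param theta_true Tortuosity used for the truth simulation.
#' @param gas_front_depth Emplacement depth of reservoir methane, mbsf.
#' @param true_ch4_bottom Reservoir dissolved methane, mol m-3 (the
#'   solubility ceiling by default).
#' @param ch4_bottom_weak Pre-pulse bottom methane, mol m-3.
#' @param noise_sd Gaussian noise standard deviation, mol m-3.
#' @param sampling_depths Depths sampled, m.
#' @param seed RNG seed (integer) for reproducibility.
#' @return List of class `"synthetic_profile_spec"`.
#' @export
synthetic_profile_spec <- function(true_onset = 18, theta_true = 2.2,
                                   gas_front_depth = 2.0,
                                   true_ch4_bottom = 64,
                                   ch4_bottom_weak = 15,
                                   noise_sd = 0.3,
                                   sampling_depths = seq(0.05, 3, by = 0.1),
                                   seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(as.list(environment()), class = "synthetic_profile_spec")
}

#' Generate a synthetic porewater dataset and its truth record
#'
#' Runs the forward reduced model with the spec's true parameters, samples
#' the sulfate (and methane) profiles at the sampling depths, adds
#' independent Gaussian noise, and clips at zero.  The generating truth is
#' returned alongside but is never consulted by the estimator.
#'
#' @param spec A [synthetic_profile_spec()].
#' @param config A [reduced_model_config()]; its weak/strong methane values
#'   are overridden by the spec.
#' @param forward Optional precomputed [synthetic_forward_run()] for this
#'   spec/config, so replicate ensembles that differ only in `seed` do not
#'   re-simulate the (identical) noiseless truth.
#' @return List with `profile` (a `"porewater_profile"` of SO4 and CH4
#'   rows), `truth` (true onset, theta, gas front, weak methane, hydrate
#'   depth = gas front, noiseless fields), and `spec`.
#' @export
generate_porewater_dataset <- function(spec, config = reduced_model_config(),
                                       forward = NULL) {
  stopifnot(inherits(spec, "synthetic_profile_spec"))
  if (is.null(forward)) forward <- synthetic_forward_run(spec, config)
  init <- forward$init; traj <- forward$traj
  zc <- init$column$cell_centres
  so4_true <- approx(zc, traj$final$so4, xout = spec$sampling_depths, rule = 2)$y
  ch4_true <- approx(zc, traj$final$ch4, xout = spec$sampling_depths, rule = 2)$y
  set.seed(spec$seed)
  so4_obs <- pmax(so4_true + rnorm(length(so4_true), 0, spec$noise_sd), 0)
  ch4_obs <- pmax(ch4_true + rnorm(length(ch4_true), 0, spec$noise_sd), 0)
  prof <- porewater_profile(
    depth_mbsf = rep(spec$sampling_depths, 2),
    species = rep(c("SO4", "CH4"), each = length(spec$sampling_depths)),
    concentration = c(so4_obs, ch4_obs),
    provenance = "simulated")
  list(profile = prof,
       truth = list(onset = spec$true_onset, theta = spec$theta_true,
                    gas_front_depth = spec$gas_front_depth,
                    hydrate_depth = spec$gas_front_depth,
                    ch4_bottom_weak = spec$ch4_bottom_weak,
                    ch4_bottom_strong = spec$true_ch4_bottom,
                    so4_noiseless = so4_true, ch4_noiseless = ch4_true,
                    smtz = smtz_depth(zc, traj$final$so4)),
       spec = spec)
}

#' Noiseless forward simulation behind a synthetic dataset
#'
#' Spin-up at the spec's true tortuosity followed by the methane pulse for
#' the true onset duration; the deterministic part of
#' [generate_porewater_dataset()].
#'
#' @param spec A [synthetic_profile_spec()].
#' @param config A [reduced_model_config()].
#' @return List with the spun-up `init` state and the pulse `traj`.
#' @export
synthetic_forward_run <- function(spec, config = reduced_model_config()) {
  stopifnot(inherits(spec, "synthetic_profile_spec"))
  config$ch4_bottom_weak <- spec$ch4_bottom_weak
  config$ch4_bottom_strong <- spec$true_ch4_bottom
  config$gas_front_depth <- spec$gas_front_depth
  init <- spin_up_initial_state(config, spec$theta_true)
  traj <- simulate_pulse(init, duration = spec$true_onset,
                         snapshot_times = spec$true_onset)
  list(init = init, traj = traj)
}

#' Specification of a synthetic bottom-water temperature record
#'
#' Seasonal sinusoid with Gaussian jitter and Poisson-timed positive
#' anomalies, emulating multi-decadal hydrographic records with occasional
#' warm-water intrusions.
#'
#' @param mean,amplitude Seasonal cycle, degC.
#' @param jitter_sd Gaussian measurement/variability jitter, degC.
#' @param anomaly_rate Expected anomalies per year.
#' @param anomaly_magnitude Peak anomaly excess, degC.
#' @param span Record length, years.
#' @param samples_per_year Average (irregular) sampling density.
#' @param seed RNG seed.
#' @return List of class `"synthetic_temperature_spec"`.
#' @export
synthetic_temperature_spec <- function(mean = 1.25, amplitude = 3.25,
                                       jitter_sd = 0.3, anomaly_rate = 0.5,
                                       anomaly_magnitude = 1.0, span = 50,
                                       samples_per_year = 12, seed = 1L) {
  structure(as.list(environment()), class = "synthetic_temperature_spec")
}

#' Generate a synthetic bottom-water temperature record
#'
#' @param spec A [synthetic_temperature_spec()].
#' @return Data frame with `date` (decimal years) and `temperature_C`.
#' @export
generate_temperature_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_temperature_spec"))
  set.seed(spec$seed)
  n <- rpois(1, spec$span * spec$samples_per_year)
  t <- sort(runif(n, 0, spec$span))
  base <- spec$mean + spec$amplitude * sin(2 * pi * (t - 0.43)) +
    rnorm(n, 0, spec$jitter_sd)
  n_anom <- rpois(1, spec$anomaly_rate * spec$span)
  if (n_anom > 0) {
    # overlapping events peak rather than stack, bounding the excess by the
    # anomaly magnitude
    excess <- rep(0, n)
    t_anom <- runif(n_anom, 0, spec$span)
    for (ta in t_anom) {
      sel <- abs(t - ta) < 0.05
      excess[sel] <- pmax(excess[sel],
                          spec$anomaly_magnitude * runif(sum(sel), 0.5, 1))
    }
    base <- base + excess
  }
  data.frame(date = t, temperature_C = base)
}
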