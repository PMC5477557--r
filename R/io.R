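#' Depth-indexed porewater concentration table
#'
#' Long-format container: one row per (depth, species) pair, concentrations
#' in mol m-3 of porewater (numerically equal to mM).
#'
#' @param depth_mbsf Depths, m below seafloor (non-negative).
#' @param species Species labels (e.g. `"SO4"`, `"CH4"`, `"TA"`).
#' @param concentration Concentrations, mol m-3 (non-negative).
#' @param provenance `"measured"` or `"simulated"`.
#' @return Data frame of class `"porewater_profile"`.
#' @export
porewater_profile <- function(depth_mbsf, species, concentration,
                              provenance = c("measured", "simulated")) {
  provenance <- match.arg(provenance)
  if (any(depth_mbsf < 0)) stop("depths must be non-negative")
  if (any(concentration < 0)) stop("concentrations must be non-negative")
  df <- data.frame(depth_mbsf = depth_mbsf, species = as.character(species),
                   concentration = concentration)
  df <- df[order(df$species, df$depth_mbsf), ]
  rownames(df) <- NULL
  structure(df, provenance = provenance, units = "mol m-3",
            class = c("porewater_profile", "data.frame"))
}

.KNOWN_SPECIES <- c("SO4", "HS", "TA", "Fe2", "Ca", "Mg", "NH4", "CH4",
                    "Ac", "H2", "Glu")

#' Read a porewater profile CSV
#'
#' Expected columns: `depth_mbsf`, `species`, `concentration_mM` (header
#' required, UTF-8, "." decimal).  1 mM is taken as 1 mol m-3.  Rows are
#' sorted by depth within species; duplicate (depth, species) pairs,
#' missing columns, non-numeric cells and negative depths are errors naming
#' the offending rows.  Unknown species names are preserved and flagged in
#' the `"unknown_species"` attribute.
#'
#' @param path CSV file path.
#' @return A [porewater_profile()] (provenance `"measured"`).
#' @examples
#' prof <- read_profile_csv(system.file("extdata", "synthetic_core.csv",
#'                                      package = "seepsim"))
#' head(prof)
#' @export
read_profile_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("depth_mbsf", "species", "concentration_mM")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("parse error: missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("depth_mbsf", "concentration_mM")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (any(is.na(v)))
      stop(sprintf("parse error: non-numeric or missing '%s' at row(s) %s",
                   col, paste(utils::head(which(is.na(v)), 5), collapse = ", ")))
    raw[[col]] <- v
  }
  bad <- which(raw$depth_mbsf < 0)
  if (length(bad) > 0)
    stop("parse error: negative depth at row(s) ", paste(bad, collapse = ", "))
  key <- paste(raw$depth_mbsf, raw$species)
  if (anyDuplicated(key))
    stop("parse error: duplicate (depth, species) record at row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  prof <- porewater_profile(raw$depth_mbsf, raw$species, raw$concentration_mM,
                            provenance = "measured")
  unknown <- setdiff(unique(prof$species), .KNOWN_SPECIES)
  if (length(unknown) > 0) {
    warning("unknown species preserved: ", paste(unknown, collapse = ", "))
    attr(prof, "unknown_species") <- unknown
  }
  prof
}

#' Write a porewater profile CSV
#'
#' Inverse of [read_profile_csv()]; full double precision is retained so a
#' write/read round trip is lossless.
#'
#' @param profile A [porewater_profile()] (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(depth_mbsf = format(profile$depth_mbsf, digits = 17),
                   species = profile$species,
                   concentration_mM = format(profile$concentration, digits = 17))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All physical and kinetic constants with their defaults, as a plain list
#' that YAML/JSON configs are validated against and merged into.
#'
#' @return Named list.
#' @export
default_run_config <- function() {
  list(seconds_per_year = SECONDS_PER_YEAR,
       water_depth = 380, salinity = 35,
       solubility_mode = "correlation", kappa_mode = "paper_constant",
       seed = 1L,
       reduced = list(length = 60, dx = 0.025, porosity = 0.7, dt = 0.01,
                      tortuosities = c(1.5, 2.2), T_bottom_water = 0.56,
                      sulfate_top = 28, ch4_bottom_weak = 15,
                      ch4_bottom_strong = 64, gas_front_depth = NULL),
       heat = list(mean = 1.25, amplitude = 3.25, geotherm_gradient = 0.044,
                   dt = 0.05, dx = 0.025, length = 60),
       scenario = list(id = "Scen4"))
}

#' Read a YAML or JSON run configuration
#'
#' Unknown top-level keys are an error (schema validation before compute);
#' supplied keys override the defaults from [default_run_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Merged configuration list with attribute `"overridden"` listing
#'   the keys the file set.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml, .yml or .json")
  if (is.null(cfg)) cfg <- list()
  defaults <- default_run_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  merged <- modifyList(defaults, cfg)
  attr(merged, "overridden") <- names(cfg)
  merged
}

#' Write the fully-resolved configuration next to run outputs
#'
#' Freezes the configuration (and an R/package version stamp) as JSON so
#' every run records exactly what it used.
#'
#' @param config Configuration list.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_resolved_config <- function(config, path) {
  stamp <- list(config = config,
                r_version = R.version.string,
                package_version = as.character(utils::packageVersion("seepsim")))
  jsonlite::write_json(stamp, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Command-line dispatcher
#'
#' Thin front end over the package functions, used by the `seepsim` script in
#' `exec/`.  Subcommands: `fit-onset`, `simulate-reduced`, `simulate-heat`,
#' `run-scenario`, `gen-synthetic`.  All randomness is seeded from the
#' configuration (`--seed` override).
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code (0 success, 2 usage error, 1 failure).
#' @export
cli_dispatch <- function(argv = character()) {
  usage <- function() {
    cat("usage: seepsim <fit-onset|simulate-reduced|simulate-heat|run-scenario|gen-synthetic> [--config FILE] [--out DIR] [options]\n")
    2L
  }
  if (length(argv) < 1) return(usage())
  cmd <- argv[1]
  opts <- .parse_cli_opts(argv[-1])
  if (is.null(opts)) return(usage())
  cfg <- tryCatch({
    if (!is.null(opts$config)) read_run_config(opts$config) else default_run_config()
  }, error = function(e) e)
  if (inherits(cfg, "error")) {
    message("error: config: ", conditionMessage(cfg)); return(1L)
  }
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  out_dir <- if (!is.null(opts$out)) opts$out else "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  res <- tryCatch({
    set.seed(cfg$seed)
    switch(cmd,
      "fit-onset" = {
        if (is.null(opts$profile)) stop("usage-error: --profile is required")
        prof <- read_profile_csv(opts$profile)
        rc <- do.call(reduced_model_config,
                      cfg$reduced[!vapply(cfg$reduced, is.null, TRUE)])
        fit <- fit_onset(prof, rc,
                         hydrate_depth = if (!is.null(opts$`hydrate-depth`))
                           as.numeric(opts$`hydrate-depth`) else NULL)
        jsonlite::write_json(
          list(site_id = fit$site_id,
               onset_years_by_tortuosity = as.list(fit$onset_years_by_tortuosity),
               onset_interval = fit$onset_interval,
               fitted_ch4_bottom = fit$fitted_ch4_bottom,
               misfit = fit$misfit,
               saturation_depth = fit$saturation_depth),
          file.path(out_dir, "onset.json"), auto_unbox = TRUE, digits = NA)
        0L
      },
      "simulate-reduced" = {
        rc <- do.call(reduced_model_config,
                      cfg$reduced[!vapply(cfg$reduced, is.null, TRUE)])
        init <- spin_up_initial_state(rc, rc$tortuosities[1])
        dur <- if (!is.null(opts$duration)) as.numeric(opts$duration) else 100
        traj <- simulate_pulse(init, dur,
                               gas_front_depth = rc$gas_front_depth)
        prof <- porewater_profile(
          rep(init$column$cell_centres, 2),
          rep(c("SO4", "CH4"), each = init$column$n_cells),
          c(traj$final$so4, traj$final$ch4), provenance = "simulated")
        write_profile_csv(prof, file.path(out_dir, "reduced_profiles.csv"))
        0L
      },
      "simulate-heat" = {
        kind <- if (!is.null(opts$scenario)) opts$scenario else "seasonal"
        if (!kind %in% c("seasonal", "fast", "slow"))
          stop("usage-error: --scenario must be seasonal, fast or slow")
        rep <- run_warming_scenario(
          kind,
          forcing = temperature_forcing(mean = cfg$heat$mean,
                                        amplitude = cfg$heat$amplitude),
          geotherm_gradient = cfg$heat$geotherm_gradient)
        jsonlite::write_json(
          list(kind = kind,
               max_destabilization_depth = rep$max_destabilization_depth,
               time_to_full_column_destabilization =
                 rep$time_to_full_column_destabilization),
          file.path(out_dir, "heat_report.json"), auto_unbox = TRUE, digits = NA)
        0L
      },
      "run-scenario" = {
        id <- if (!is.null(opts$id)) opts$id else cfg$scenario$id
        sc <- run_scenario(scenario_spec(id))
        z <- sc$column$cell_centres
        prof <- porewater_profile(
          rep(z, length(sc$state$solutes)),
          rep(names(sc$state$solutes), each = length(z)),
          unlist(sc$state$solutes, use.names = FALSE), provenance = "simulated")
        write_profile_csv(prof, file.path(out_dir, paste0(id, "_profiles.csv")))
        shp <- classify_profile_shape(z[z <= 2], sc$state$solutes$SO4[z <= 2])
        jsonlite::write_json(list(id = id, so4_shape = shp$classification,
                                  kink_depth = shp$kink_depth),
                             file.path(out_dir, paste0(id, "_shape.json")),
                             auto_unbox = TRUE, digits = NA)
        0L
      },
      "gen-synthetic" = {
        spec <- synthetic_profile_spec(seed = cfg$seed)
        ds <- generate_porewater_dataset(spec)
        write_profile_csv(ds$profile, file.path(out_dir, "synthetic_profile.csv"))
        jsonlite::write_json(ds$truth[c("onset", "theta", "gas_front_depth",
                                        "hydrate_depth", "smtz")],
                             file.path(out_dir, "synthetic_truth.json"),
                             auto_unbox = TRUE, digits = NA)
        ts <- generate_temperature_series(synthetic_temperature_spec(seed = cfg$seed))
        write.csv(ts, file.path(out_dir, "synthetic_temperature.csv"),
                  row.names = FALSE)
        0L
      },
      { message("error: usage-error: unknown subcommand '", cmd, "'"); 2L })
  }, error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", gsub("\n", " ", msg))
    if (grepl("usage-error", msg)) 2L else 1L
  })
  if (res == 0L)
    write_resolved_config(cfg, file.path(out_dir, "resolved_config.json"))
  res
}

.parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) return(NULL)
    key <- substring(a, 3)
    if (i + 1 > length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE; i <- i + 1
    } else {
      opts[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  opts
}
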