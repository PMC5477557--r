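#' Discretized 1-D sediment column
#'
#' Uniform (or block-wise) finite-volume grid in metres below seafloor,
#' positive downward, with per-cell porosity.  Cell centres are at the
#' midpoints of the cell widths.
#'
#' @param length Column length in m (ignored when `dx` is a vector giving the
#'   cell widths directly).
#' @param dx Cell width in m, or a vector of cell widths for a non-uniform
#'   grid.
#' @param porosity Porosity, scalar or per-cell, in (0, 1\].
#' @param tortuosity Dimensionless tortuosity used to derive porous-medium
#'   diffusivities.
#' @return Object of class `"sediment_column"` with `n_cells`, `dx` (vector),
#'   `cell_centres`, `porosity` (vector), `tortuosity`, `length`.
#' @examples
#' sediment_column(60, 0.025)
#' @export
sediment_column <- function(length = 60, dx = 0.025, porosity = 0.7,
                            tortuosity = 1.5) {
  if (length(dx) == 1) {
    n <- round(length / dx)
    if (abs(n * dx - length) > 1e-9) stop("length must be a multiple of dx")
    dx <- rep(dx, n)
  }
  n <- base::length(dx)
  if (any(dx <= 0)) stop("cell widths must be positive")
  if (any(porosity <= 0) || any(porosity > 1)) stop("porosity must lie in (0, 1]")
  porosity <- rep_len(porosity, n)
  edges <- cumsum(c(0, dx))
  structure(list(n_cells = n, dx = dx,
                 cell_centres = (edges[-1] + edges[-(n + 1)]) / 2,
                 porosity = porosity, tortuosity = tortuosity,
                 length = sum(dx)),
            class = "sediment_column")
}

#' @export
print.sediment_column <- function(x, ...) {
  cat(sprintf("sediment column: %.3g m, %d cells (dx %s m), porosity %s\n",
              x$length, x$n_cells,
              if (length(unique(x$dx)) == 1) format(x$dx[1]) else "variable",
              if (length(unique(x$porosity)) == 1) format(x$porosity[1]) else "variable"))
  invisible(x)
}

#' Solute field on a column with boundary conditions
#'
#' @param column A [sediment_column()].
#' @param concentrations Per-cell concentrations, mol m-3 (recycled).
#' @param solute_id Character label.
#' @param upper_bc,lower_bc Lists `list(type =, value =)`.  Types for the
#'   upper boundary: `"fixed-value"` (imposed at the z = 0 interface) or
#'   `"no-flux"`; the lower boundary also accepts `"fixed-gradient"`
#'   (value in units per metre).
#' @param time Elapsed model time in years.
#' @return Object of class `"field_state"`.
#' @export
field_state <- function(column, concentrations = 0, solute_id = "solute",
                        upper_bc = list(type = "no-flux", value = 0),
                        lower_bc = list(type = "no-flux", value = 0),
                        time = 0) {
  conc <- rep_len(concentrations, column$n_cells)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative")
  .check_bc(upper_bc, c("fixed-value", "no-flux"))
  .check_bc(lower_bc, c("fixed-value", "no-flux", "fixed-gradient"))
  structure(list(column = column, concentrations = conc,
                 solute_id = solute_id, upper_bc = upper_bc,
                 lower_bc = lower_bc, time = time,
                 clip_count = 0L),
            class = "field_state")
}

.check_bc <- function(bc, allowed) {
  if (!is.list(bc) || is.null(bc$type) || !(bc$type %in% allowed))
    stop("boundary condition must be list(type=, value=) with type in: ",
         paste(allowed, collapse = ", "))
  invisible(TRUE)
}

.bc_code <- function(type) {
  switch(type, "fixed-value" = 0L, "no-flux" = 1L, "fixed-gradient" = 2L)
}

#' One Crank-Nicolson diffusion step
#'
#' Advances `d(phi C)/dt = d/dz(phi D_s dC/dz)` by one implicit
#' Crank-Nicolson step (tridiagonal solve, second order in space) with the
#' state's boundary conditions.  Fixed-value boundaries are imposed at the
#' interfaces via ghost cells, not at the first cell centre.
#'
#' @param state A [field_state()].
#' @param D_s Porous-medium diffusivity, m2 yr-1 (scalar or per-cell).
#' @param dt Time step in years.
#' @param bc_next Optional list with elements `upper`/`lower` giving boundary
#'   values at `t + dt` for time-varying forcing (defaults to the current
#'   values).
#' @return The advanced `field_state`.
#' @export
cn_diffusion_step <- function(state, D_s, dt, bc_next = NULL) {
  if (dt <= 0) stop("dt must be positive")
  if (any(D_s < 0)) stop("D_s must be non-negative")
  col <- state$column
  Ds <- rep_len(D_s, col$n_cells)
  u1 <- if (!is.null(bc_next$upper)) bc_next$upper else state$upper_bc$value
  l1 <- if (!is.null(bc_next$lower)) bc_next$lower else state$lower_bc$value
  newc <- cn_step_general(state$concentrations, col$porosity, Ds, col$dx, dt,
                          .bc_code(state$upper_bc$type),
                          state$upper_bc$value, u1,
                          .bc_code(state$lower_bc$type),
                          state$lower_bc$value, l1)
  state$concentrations <- newc
  state$upper_bc$value <- u1
  state$lower_bc$value <- l1
  state$time <- state$time + dt
  state
}

#' One upwind advection step
#'
#' First-order upwind transport; positive velocity moves material downward
#' (into the sediment).  Errors when `|v| dt > dx` (CFL); callers should
#' sub-step.
#'
#' @param state A [field_state()].
#' @param velocity Advection velocity in m yr-1.
#' @param dt Time step in years.
#' @param inflow Concentration carried across the inflow boundary (defaults
#'   to the fixed boundary value on that side, else 0).
#' @return The advanced `field_state`.
#' @export
advection_step <- function(state, velocity, dt, inflow = NULL) {
  if (dt <= 0) stop("dt must be positive")
  col <- state$column
  if (is.null(inflow)) {
    inflow <- if (velocity > 0 && state$upper_bc$type == "fixed-value")
      state$upper_bc$value
    else if (velocity < 0 && state$lower_bc$type == "fixed-value")
      state$lower_bc$value
    else 0
  }
  state$concentrations <- upwind_step(state$concentrations, velocity,
                                      col$dx, dt, inflow)
  state$time <- state$time + dt
  state
}

#' Apply explicit (operator-split) kinetics to one or more fields
#'
#' Updates each field by `C <- max(C + dt * R, 0)` where the rate function
#' returns per-cell rates in mol m-3 yr-1 for each solute.  Negative
#' undershoots are clipped to zero and counted on each state (`clip_count`).
#'
#' @param states A named list of [field_state()] objects.
#' @param rate_fn `function(conc_list) -> named list/matrix of rates` in the
#'   same order/names as `states`.
#' @param dt Time step in years.
#' @return The list of advanced states.
#' @export
apply_kinetics <- function(states, rate_fn, dt) {
  conc <- lapply(states, `[[`, "concentrations")
  rates <- rate_fn(conc)
  for (nm in names(states)) {
    r <- rates[[nm]]
    if (is.null(r)) next
    if (any(!is.finite(r))) stop("kinetics error: rate function returned non-finite values")
    newc <- states[[nm]]$concentrations + dt * r
    nclip <- sum(newc < 0)
    states[[nm]]$concentrations <- pmax(newc, 0)
    states[[nm]]$clip_count <- states[[nm]]$clip_count + nclip
    states[[nm]]$time <- states[[nm]]$time + dt
  }
  states
}

#' Total dissolved inventory of a field
#'
#' `sum(phi * C * dx)`: the conserved quantity under no-flux boundaries and
#' zero kinetics.
#'
#' @param state A [field_state()].
#' @return Inventory in mol m-2.
#' @export
field_inventory <- function(state) {
  sum(state$column$porosity * state$concentrations * state$column$dx)
}
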