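#' Thermal model parameter set
#'
#' Lumped-volume (volume element method) temperature model: each reactor
#' volume obeys one first-law ODE combining advection, wall heat loss and
#' absorbed solar radiation; the column additionally holds the
#' heat-exchanger sink. The empirical internal-convection correlations of
#' the physical plant are collapsed into a single combined wall conductance
#' per unit outer area.
#'
#' @param fluid_density Culture density, kg/m3.
#' @param fluid_heat_capacity Culture specific heat, J/(kg K).
#' @param wall_conductance Combined wall + external film conductance
#'   `U_wall`, W/(m2 K), referenced to the outer tube area.
#' @param solar_absorptivity Fraction of incident irradiance absorbed by the
#'   culture, `[0, 1]`.
#' @param hx_UA Heat-exchanger overall conductance `UA`, W/K.
#' @param cooling_water_cp Cooling water specific heat, J/(kg K).
#' @param n_thermal_volumes Number of lumped loop volumes; defaults to the
#'   mass-balance element count when `NULL` (co-located grids).
#' @return List of class `pbr_thermal`.
#' @export
thermal_params <- function(fluid_density = 1000, fluid_heat_capacity = 4186,
                           wall_conductance = 15, solar_absorptivity = 0.35,
                           hx_UA = 500, cooling_water_cp = 4186,
                           n_thermal_volumes = NULL) {
  if (solar_absorptivity < 0 || solar_absorptivity > 1) {
    stop("`solar_absorptivity` must be in [0, 1]", call. = FALSE)
  }
  vals <- c(fluid_density, fluid_heat_capacity, hx_UA, cooling_water_cp)
  if (any(vals <= 0) || wall_conductance < 0) {
    stop("thermal parameters must be positive", call. = FALSE)
  }
  structure(
    list(
      fluid_density = fluid_density,
      fluid_heat_capacity = fluid_heat_capacity,
      wall_conductance = wall_conductance,
      solar_absorptivity = solar_absorptivity,
      hx_UA = hx_UA, cooling_water_cp = cooling_water_cp,
      n_thermal_volumes = n_thermal_volumes
    ),
    class = "pbr_thermal"
  )
}

# Per-volume thermal geometry for the loop discretisation.
thermal_geometry <- function(geom, thermal) {
  n <- if (is.null(thermal$n_thermal_volumes)) geom$n_elements else
    as.integer(thermal$n_thermal_volumes)
  if (n < 1) stop("`n_thermal_volumes` must be >= 1", call. = FALSE)
  len <- geom$tube_length_m / n
  list(
    n = n,
    len = len,
    v_elem = geom$a_tube * len,
    a_out = pi * geom$tube_diameter_m * len, # outer wall area
    a_proj = geom$tube_diameter_m * len, # projected (radiation) area
    a_out_col = pi * geom$column_diameter_m * geom$column_height_m,
    a_proj_col = geom$column_diameter_m * geom$column_height_m
  )
}

#' First-law energy rate of one lumped volume
#'
#' `dT/dt = [m_dot cp (T_up - T) + U_wall A_out (T_amb - T) + alpha A_proj G]
#' / (rho V cp)` for a tube volume of given length and diameter.
#'
#' @param T_i Volume temperature, C.
#' @param T_upstream Upstream (inflowing) temperature, C.
#' @param mass_flow Culture mass flow, kg/s.
#' @param irradiance Global irradiance, W/m2.
#' @param ambient Ambient temperature, C.
#' @param length,diameter Volume dimensions, m.
#' @param thermal A [thermal_params()] object.
#' @return Temperature rate, K/s.
#' @export
volume_energy_rate <- function(T_i, T_upstream, mass_flow, irradiance,
                               ambient, length, diameter, thermal) {
  if (length <= 0 || diameter <= 0) {
    stop("volume length and diameter must be > 0", call. = FALSE)
  }
  v <- pi * (diameter / 2)^2 * length
  a_out <- pi * diameter * length
  a_proj <- diameter * length
  cp <- thermal$fluid_heat_capacity
  (mass_flow * cp * (T_upstream - T_i) +
     thermal$wall_conductance * a_out * (ambient - T_i) +
     thermal$solar_absorptivity * a_proj * irradiance) /
    (thermal$fluid_density * v * cp)
}

#' Heat removed by the column heat-exchanger coil
#'
#' Effectiveness-NTU model of the cooling coil in the mixing unit:
#' `Q = eps * m_dot_c * cp_w * (T_column - T_cool_in)` with
#' `eps = 1 - exp(-UA / (m_dot_c cp_w))`. Zero at zero flow; the sign
#' follows `T_column - T_cool_in`.
#'
#' @param T_column Column culture temperature, C.
#' @param T_cool_in Cooling-water inlet temperature, C.
#' @param cooling_flow Cooling-water mass flow, kg/s (>= 0).
#' @param thermal A [thermal_params()] object.
#' @return Heat duty removed from the culture, W.
#' @export
heat_exchanger_duty <- function(T_column, T_cool_in, cooling_flow, thermal) {
  if (any(cooling_flow < 0)) stop("`cooling_flow` must be >= 0", call. = FALSE)
  cpw <- thermal$cooling_water_cp
  eff <- ifelse(cooling_flow > 0,
    1 - exp(-thermal$hx_UA / (cooling_flow * cpw)), 0
  )
  eff * cooling_flow * cpw * (T_column - T_cool_in)
}

#' Advance the thermal state by one explicit step
#'
#' All loop volumes are chained in flow order (the column outlet feeds loop
#' volume 1, the last loop volume feeds the column); the column volume
#' carries the heat-exchanger sink. Explicit Euler with automatic
#' sub-stepping to keep the update inside the linear-stability bound.
#'
#' @param state List with `T_loop` (numeric vector, C), `T_column` (C),
#'   `cooling_water_inlet` (C), `cooling_water_flow` (kg/s).
#' @param irradiance Global irradiance, W/m2.
#' @param ambient Ambient temperature, C.
#' @param mass_flow Circulating culture mass flow, kg/s.
#' @param dt Time step, s (> 0).
#' @param geom A [pbr_geometry()] object.
#' @param thermal A [thermal_params()] object.
#' @param column_sun Logical; expose the column to solar gain (default TRUE).
#' @return Updated state list.
#' @export
step_thermal <- function(state, irradiance, ambient, mass_flow, dt,
                         geom, thermal, column_sun = TRUE) {
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  tg <- thermal_geometry(geom, thermal)
  rho_cp <- thermal$fluid_density * thermal$fluid_heat_capacity
  c_elem <- rho_cp * tg$v_elem # J/K per loop volume
  c_col <- rho_cp * geom$v_column_liq
  cp <- thermal$fluid_heat_capacity
  # stability: advective and wall-loss time constants
  tau_adv <- if (mass_flow > 0) {
    tg$v_elem * thermal$fluid_density / mass_flow
  } else {
    Inf
  }
  tau_wall <- if (thermal$wall_conductance > 0) {
    c_elem / (thermal$wall_conductance * tg$a_out)
  } else {
    Inf
  }
  dt_max <- 0.5 * min(tau_adv, tau_wall)
  n_sub <- max(1L, ceiling(dt / dt_max))
  h <- dt / n_sub
  T_loop <- state$T_loop
  if (length(T_loop) != tg$n) {
    stop("`T_loop` length must equal n_thermal_volumes", call. = FALSE)
  }
  T_col <- state$T_column
  uw <- thermal$wall_conductance
  alpha <- thermal$solar_absorptivity
  for (s in seq_len(n_sub)) {
    up <- c(T_col, T_loop[-tg$n])
    dT <- (mass_flow * cp * (up - T_loop) +
             uw * tg$a_out * (ambient - T_loop) +
             alpha * tg$a_proj * irradiance) / c_elem
    q_hx <- heat_exchanger_duty(T_col, state$cooling_water_inlet,
      state$cooling_water_flow, thermal
    )
    sun_col <- if (column_sun) alpha * tg$a_proj_col * irradiance else 0
    dT_col <- (mass_flow * cp * (T_loop[tg$n] - T_col) +
                 uw * tg$a_out_col * (ambient - T_col) +
                 sun_col - q_hx) / c_col
    if (any(abs(c(dT, dT_col)) * h > 5)) {
      stop("thermal step unstable (|dT| > 5 K per step); reduce dt",
        call. = FALSE
      )
    }
    T_loop <- T_loop + h * dT
    T_col <- T_col + h * dT_col
  }
  if (any(c(T_loop, T_col) < -10) || any(c(T_loop, T_col) > 80)) {
    warning("culture temperature outside the plausible range [-10, 80] C")
  }
  state$T_loop <- T_loop
  state$T_column <- T_col
  state
}
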