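#' Run a photobioreactor simulation
#'
#' Deterministic fixed-step simulation of the full plant with operator
#' splitting per base step: controllers (at their sampling or event
#' instants) -> actuators -> reaction and gas-liquid transfer -> CO2
#' injection -> upwind advection -> thermal update -> harvest events.
#' Advection and the thermal model sub-step automatically when the base
#' step would violate their stability bounds.
#'
#' @param cfg A [pbr_config()] object.
#' @param forcing Optional `pbr_forcing` data.frame (from
#'   [generate_forcing()] or [load_profile()]); when `NULL` the synthetic
#'   model in the configuration is used.
#' @param check_negatives Stop with a step-size error if any concentration
#'   goes negative (default TRUE).
#' @return A `pbr_result`: data.frame of logged series (one row per
#'   `output_stride` steps) with the configuration, final state and
#'   conservation counters attached as attributes. Columns include time,
#'   irradiance, pH at the three sensors (column entry, mid-loop,
#'   pre-injection), loop and column temperatures, dissolved O2 at the
#'   column and loop end, mean biomass, gas mole fractions, CO2
#'   injected/lost, O2 production and the three controller commands.
#' @examples
#' cfg <- pbr_config(simulation = list(duration_days = 0.02))
#' res <- run_simulation(cfg)
#' @export
run_simulation <- function(cfg, forcing = NULL, check_negatives = TRUE) {
  stopifnot(inherits(cfg, "pbr_config"))
  obj <- attr(cfg, "objects")
  geom <- obj$geom
  kin <- obj$kin
  chem <- obj$chem
  thermal <- obj$thermal
  sim <- cfg$simulation
  env <- cfg$environment
  op <- cfg$operation

  dt <- sim$dt_s
  nsteps <- round(sim$duration_days * 86400 / dt)
  times <- (seq_len(nsteps) - 1) * dt

  # ---- forcing, precomputed on the step grid ----
  if (is.null(forcing)) {
    day <- (sim$start_day_of_year - 1 + times %/% 86400) %% 365 + 1
    hour <- (times %% 86400) / 3600
    cz <- solar_cos_zenith(env$latitude, solar_declination(day), hour)
    Gvec <- env$clearness_index * solar_extraterrestrial(day, cz)
    Tambvec <- ambient_temperature(times, env$ambient_mean_C,
      env$ambient_amplitude_C, env$ambient_peak_hour
    )
  } else {
    fi <- forcing_interpolator(forcing)
    Gvec <- fi$global(times)
    Tambvec <- fi$ambient(times)
  }

  # ---- unpack constants ----
  n <- geom$n_elements
  v_elem <- geom$v_elem
  v_col <- geom$v_column_liq
  n_gas <- geom$n_gas_mol
  dx <- geom$dx
  a_tube <- geom$a_tube
  d_tube <- geom$tube_diameter_m
  ka <- kin$extinction_coeff
  rmax <- kin$r_o2_max
  hn <- kin$hill_n
  ihn <- kin$i_half^hn
  o2i <- kin$o2_inhibition_conc
  mexp <- kin$inhibition_exponent
  yld <- kin$yield_x_per_o2
  pq <- kin$photosynthetic_quotient
  resp <- kin$respiration_rate
  clf <- kin$column_light_factor
  k1 <- chem$k1
  k2 <- chem$k2
  kw <- chem$kw
  alk <- chem$alkalinity
  ho2 <- chem$henry_o2
  hco2 <- chem$henry_co2
  klao2 <- chem$kla_o2
  klaco2 <- chem$kla_co2
  eff <- chem$co2_absorption_eff
  f_in <- op$air_flow_L_min / GAS_MOLAR_VOLUME_L / 60
  yin_o2 <- op$air_y_o2
  yin_co2 <- op$air_y_co2

  tg <- thermal_geometry(geom, thermal)
  n_th <- tg$n
  cp <- thermal$fluid_heat_capacity
  rho <- thermal$fluid_density
  c_elem_th <- rho * cp * tg$v_elem
  c_col_th <- rho * cp * v_col
  uw_aout <- thermal$wall_conductance * tg$a_out
  uw_aout_col <- thermal$wall_conductance * tg$a_out_col
  al_aproj <- thermal$solar_absorptivity * tg$a_proj
  al_aproj_col <- thermal$solar_absorptivity * tg$a_proj_col
  hx_ua <- thermal$hx_UA
  cpw <- thermal$cooling_water_cp
  t_cool_in <- cfg$thermal$cooling_water_inlet_C
  # thermal sub-stepping sized for the fastest admissible flow
  mdot_max <- rho * op$pump_max_velocity_m_s * a_tube
  tau_th <- min(
    if (mdot_max > 0) tg$v_elem * rho / mdot_max else Inf,
    if (thermal$wall_conductance > 0) c_elem_th / uw_aout else Inf
  )
  n_sub_th <- max(1L, ceiling(dt / (0.5 * tau_th)))
  h_th <- dt / n_sub_th

  # ---- initial state ----
  o2_sat <- ho2 * yin_o2
  o2_0 <- if (is.na(op$initial_do2_mol_m3)) o2_sat else op$initial_do2_mol_m3
  ct_0 <- ct_from_ph(op$initial_ph, chem)
  cb <- rep(op$initial_biomass_g_m3, n)
  o2 <- rep(o2_0, n)
  ct <- rep(ct_0, n)
  cb_c <- op$initial_biomass_g_m3
  o2_c <- o2_0
  ct_c <- ct_0
  y_o2 <- yin_o2
  y_co2 <- yin_co2
  h_c <- 10^(3 - op$initial_ph)
  Tl <- rep(op$initial_temperature_C, n_th)
  T_c <- op$initial_temperature_C

  # ---- controllers & actuators ----
  ctl <- cfg$control
  act <- list(
    ph = actuator_model(op$co2_max_flow_L_min, ctl$ph$actuator_tau_s,
      0, op$co2_max_flow_L_min
    ),
    flow = actuator_model(op$pump_max_velocity_m_s, ctl$flow$actuator_tau_s,
      0, op$pump_max_velocity_m_s
    ),
    temp = actuator_model(op$cooling_max_flow_kg_s, ctl$temp$actuator_tau_s,
      0, op$cooling_max_flow_kg_s
    )
  )
  picfg <- lapply(ctl[c("ph", "flow", "temp")], function(cc) {
    pi_config(cc$kp, cc$ti, cc$ts)
  })
  # manual commands precomputed per step (piecewise-constant schedules)
  manual_cmd <- function(cc, gain) {
    val <- rep(cc$manual_value, nsteps)
    if (!is.null(cc$schedule)) {
      for (r in seq_len(nrow(cc$schedule))) {
        val[times >= cc$schedule$time_h[r] * 3600] <- cc$schedule$flow_L_min[r]
      }
    }
    pmin(pmax(val / gain, 0), 1)
  }
  cmd_manual <- list(
    ph = manual_cmd(ctl$ph, op$co2_max_flow_L_min),
    flow = manual_cmd(ctl$flow, op$pump_max_velocity_m_s),
    temp = manual_cmd(ctl$temp, op$cooling_max_flow_kg_s)
  )
  ts_steps <- vapply(picfg, function(p) max(1L, as.integer(round(p$ts / dt))),
    1L
  )
  st <- list(ph = pi_state(), flow = pi_state(), temp = pi_state())
  onoff_prev <- c(ph = 0, flow = 0, temp = 0)
  u <- c(ph = cmd_manual$ph[1], flow = cmd_manual$flow[1],
         temp = cmd_manual$temp[1])
  x_co2 <- 0 # L/min
  x_vel <- op$velocity_m_s
  x_cool <- 0
  decay <- vapply(act, function(a) {
    if (a$time_constant == 0) 1 else 1 - exp(-dt / a$time_constant)
  }, 0)

  # warm pH states for the loop sensors (logged only)
  h_entry <- h_c
  h_mid <- h_c
  i_mid <- max(1L, as.integer(round(n / 2)))

  # ---- harvest schedule ----
  hv <- cfg$harvest
  hv_steps <- if (nrow(hv) > 0) as.integer(round(hv$time_h * 3600 / dt)) + 1L
    else integer(0)
  medium <- list(
    total_inorganic_carbon = ct_from_ph(8, chem),
    dissolved_o2 = o2_sat
  )
  harvested_total <- 0

  # ---- counters (mol; biomass in g) ----
  c_gross <- 0; c_resp <- 0
  c_inj_sup <- 0; c_inj_dis <- 0; c_inj_loss <- 0
  c_abs_o2 <- 0; c_abs_co2 <- 0
  c_gas_in_o2 <- 0; c_gas_in_co2 <- 0
  c_vent_o2 <- 0; c_vent_co2 <- 0
  c_harv_ct <- 0; c_harv_o2 <- 0
  stock0 <- c(
    ct = sum(ct) * v_elem + ct_c * v_col,
    o2 = sum(o2) * v_elem + o2_c * v_col,
    cb = sum(cb) * v_elem + cb_c * v_col,
    gas_o2 = n_gas * y_o2, gas_co2 = n_gas * y_co2
  )

  # ---- logging ----
  stride <- sim$output_stride
  nlog <- length(seq(1L, nsteps, by = stride))
  log_names <- c(
    "time_s", "time_h", "irradiance_Wm2", "ambient_C",
    "ph_column_entry", "ph_loop_mid", "ph_preinjection",
    "temp_loop_in_C", "temp_loop_mid_C", "temp_loop_out_C", "temp_column_C",
    "do2_column_mol_m3", "do2_loop_end_mol_m3",
    "biomass_g_m3", "gas_y_o2", "gas_y_co2",
    "co2_flow_L_min", "velocity_m_s", "cooling_flow_kg_s",
    "u_ph", "u_flow", "u_temp",
    "co2_injected_mol", "co2_injection_mol_s", "co2_losses_mol",
    "co2_vented_mol", "o2_production_mol_s", "o2_produced_mol",
    "ph_events", "harvested_g"
  )
  logm <- matrix(NA_real_, nlog, length(log_names),
    dimnames = list(NULL, log_names)
  )
  ilog <- 0L
  i_mid_th <- max(1L, as.integer(round(n_th / 2)))
  v_total <- n * v_elem + v_col

  for (k in seq_len(nsteps)) {
    t_now <- times[k]
    G <- Gvec[k]
    Tamb <- Tambvec[k]

    # ---- controllers ----
    ph_c <- 3 - log10(h_c)
    meas <- c(ph = ph_c, flow = x_vel, temp = T_c)
    for (lp in c("ph", "flow", "temp")) {
      cc <- ctl[[lp]]
      mode <- cc$mode
      if (mode == "manual") {
        u[[lp]] <- cmd_manual[[lp]][k]
      } else if (mode == "onoff") {
        onoff_prev[[lp]] <- onoff_step(meas[[lp]], cc$setpoint,
          onoff_prev[[lp]], cc$hysteresis, cc$direction
        )
        u[[lp]] <- onoff_prev[[lp]]
      } else if (mode == "pi_time") {
        if ((k - 1L) %% ts_steps[[lp]] == 0L) {
          st[[lp]] <- pi_time_step(cc$setpoint - meas[[lp]], st[[lp]],
            picfg[[lp]]
          )
        }
        u[[lp]] <- st[[lp]]$u
      } else { # pi_event
        ev <- ssod_sample(meas[[lp]], cc$setpoint, st[[lp]]$level, cc$delta)
        if (ev$event) {
          st[[lp]]$level <- ev$level
          st[[lp]]$n_events <- st[[lp]]$n_events + 1L
        }
        st[[lp]] <- pi_event_update(-st[[lp]]$level * cc$delta, dt,
          st[[lp]], picfg[[lp]]
        )
        u[[lp]] <- st[[lp]]$u
      }
    }

    # ---- actuators (exact first-order update) ----
    x_co2 <- x_co2 + (act$ph$gain * u[["ph"]] - x_co2) * decay[["ph"]]
    x_vel <- x_vel + (act$flow$gain * u[["flow"]] - x_vel) * decay[["flow"]]
    x_cool <- x_cool + (act$temp$gain * u[["temp"]] - x_cool) * decay[["temp"]]

    velocity <- x_vel
    q_liq <- velocity * a_tube
    mdot <- rho * q_liq

    # ---- reactions in the loop (explicit, from the old state) ----
    xa <- ka * d_tube * cb
    iav <- G * ifelse(xa < 1e-8, 1 - xa / 2, (1 - exp(-xa)) / xa)
    light <- iav^hn / (ihn + iav^hn)
    inhib <- pmax(0, 1 - (o2 / o2i)^mexp)
    gross <- cb * rmax * light * inhib
    respv <- cb * resp
    net <- gross - respv
    cb <- cb + dt * yld * gross
    o2 <- o2 + dt * net
    ct <- ct - dt * net / pq
    c_gross <- c_gross + sum(gross) * v_elem * dt
    c_resp <- c_resp + sum(respv) * v_elem * dt

    # ---- column reactions + gas-liquid transfer ----
    h_c <- carbonate_h_newton(h_c, ct_c, chem, iters = 2L)
    dq <- h_c * h_c + k1 * h_c + k1 * k2
    co2aq_c <- ct_c * h_c * h_c / dq
    gross_c <- if (clf > 0) {
      xac <- ka * geom$column_diameter_m * cb_c
      iavc <- clf * G *
        (if (xac < 1e-8) 1 - xac / 2 else (1 - exp(-xac)) / xac)
      cb_c * rmax * iavc^hn / (ihn + iavc^hn) *
        max(0, 1 - (o2_c / o2i)^mexp)
    } else {
      0
    }
    resp_c <- cb_c * resp
    net_c <- gross_c - resp_c
    to2 <- klao2 * (ho2 * y_o2 - o2_c)
    tco2 <- klaco2 * (hco2 * y_co2 - co2aq_c)
    cb_c <- cb_c + dt * yld * gross_c
    o2_c <- o2_c + dt * (net_c + to2)
    ct_c <- ct_c + dt * (tco2 - net_c / pq)
    c_gross <- c_gross + gross_c * v_col * dt
    c_resp <- c_resp + resp_c * v_col * dt
    c_abs_o2 <- c_abs_o2 + to2 * v_col * dt
    c_abs_co2 <- c_abs_co2 + tco2 * v_col * dt
    s_o2 <- -to2 * v_col
    s_co2 <- -tco2 * v_col
    f_out <- max(f_in + s_o2 + s_co2, 0)
    c_gas_in_o2 <- c_gas_in_o2 + f_in * yin_o2 * dt
    c_gas_in_co2 <- c_gas_in_co2 + f_in * yin_co2 * dt
    c_vent_o2 <- c_vent_o2 + f_out * y_o2 * dt
    c_vent_co2 <- c_vent_co2 + f_out * y_co2 * dt
    y_o2 <- y_o2 + dt * (f_in * yin_o2 - f_out * y_o2 + s_o2) / n_gas
    y_co2 <- y_co2 + dt * (f_in * yin_co2 - f_out * y_co2 + s_co2) / n_gas

    # ---- CO2 injection into loop element 1 ----
    inj_sup <- x_co2 / GAS_MOLAR_VOLUME_L / 60
    inj_dis <- inj_sup * eff
    ct[1] <- ct[1] + dt * inj_dis / v_elem
    c_inj_sup <- c_inj_sup + inj_sup * dt
    c_inj_dis <- c_inj_dis + inj_dis * dt
    c_inj_loss <- c_inj_loss + (inj_sup - inj_dis) * dt

    # ---- advection (upwind, conservative pairing, CFL sub-stepping) ----
    lam <- velocity * dt / dx
    n_adv <- max(1L, ceiling(lam))
    lam_s <- lam / n_adv
    lam_col_s <- q_liq * dt / v_col / n_adv
    for (s in seq_len(n_adv)) {
      cbN <- cb[n]; o2N <- o2[n]; ctN <- ct[n]
      cb <- cb + lam_s * (c(cb_c, cb[-n]) - cb)
      o2 <- o2 + lam_s * (c(o2_c, o2[-n]) - o2)
      ct <- ct + lam_s * (c(ct_c, ct[-n]) - ct)
      cb_c <- cb_c + lam_col_s * (cbN - cb_c)
      o2_c <- o2_c + lam_col_s * (o2N - o2_c)
      ct_c <- ct_c + lam_col_s * (ctN - ct_c)
    }

    # ---- thermal (VEM volumes, explicit with sub-steps) ----
    for (s in seq_len(n_sub_th)) {
      dTl <- (mdot * cp * (c(T_c, Tl[-n_th]) - Tl) + uw_aout * (Tamb - Tl) +
                al_aproj * G) / c_elem_th
      ec <- if (x_cool > 0) 1 - exp(-hx_ua / (x_cool * cpw)) else 0
      q_hx <- ec * x_cool * cpw * (T_c - t_cool_in)
      dTc <- (mdot * cp * (Tl[n_th] - T_c) + uw_aout_col * (Tamb - T_c) +
                al_aproj_col * G - q_hx) / c_col_th
      Tl <- Tl + h_th * dTl
      T_c <- T_c + h_th * dTc
    }

    # ---- harvest events ----
    if (length(hv_steps) > 0 && any(hv_steps == k)) {
      for (r in which(hv_steps == k)) {
        before <- c(
          ct = sum(ct) * v_elem + ct_c * v_col,
          o2 = sum(o2) * v_elem + o2_c * v_col
        )
        h_res <- apply_harvest(
          list(biomass = cb, dissolved_o2 = o2, total_inorganic_carbon = ct),
          list(biomass = cb_c, dissolved_o2 = o2_c,
               total_inorganic_carbon = ct_c),
          hv$fraction[r], medium, geom
        )
        cb <- h_res$loop$biomass
        o2 <- h_res$loop$dissolved_o2
        ct <- h_res$loop$total_inorganic_carbon
        cb_c <- h_res$column$biomass
        o2_c <- h_res$column$dissolved_o2
        ct_c <- h_res$column$total_inorganic_carbon
        harvested_total <- harvested_total + h_res$harvested_biomass_g
        c_harv_ct <- c_harv_ct +
          (sum(ct) * v_elem + ct_c * v_col - before[["ct"]])
        c_harv_o2 <- c_harv_o2 +
          (sum(o2) * v_elem + o2_c * v_col - before[["o2"]])
      }
    }

    if (check_negatives &&
        (o2_c < 0 || ct_c < 0 || min(o2) < 0 || min(ct) < 0 ||
           y_o2 < 0 || y_co2 < 0)) {
      stop(sprintf(
        "negative concentration at t = %.1f s (step %d); reduce dt_s",
        t_now, k
      ), call. = FALSE)
    }

    # ---- logging ----
    if ((k - 1L) %% stride == 0L) {
      ilog <- ilog + 1L
      h_entry <- carbonate_h_newton(h_entry, ct[n], chem, iters = 6L)
      h_mid <- carbonate_h_newton(h_mid, ct[i_mid], chem, iters = 6L)
      logm[ilog, ] <- c(
        t_now, t_now / 3600, G, Tamb,
        3 - log10(h_entry), 3 - log10(h_mid), 3 - log10(h_c),
        Tl[1], Tl[i_mid_th], Tl[n_th], T_c,
        o2_c, o2[n],
        (sum(cb) * v_elem + cb_c * v_col) / v_total, y_o2, y_co2,
        x_co2, velocity, x_cool,
        u[["ph"]], u[["flow"]], u[["temp"]],
        c_inj_sup, inj_sup, c_inj_loss,
        c_vent_co2, sum(gross) * v_elem + gross_c * v_col, c_gross,
        st$ph$n_events, harvested_total
      )
    }
  }

  counters <- list(
    gross_o2 = c_gross, resp_o2 = c_resp,
    inj_supplied = c_inj_sup, inj_dissolved = c_inj_dis,
    inj_losses = c_inj_loss,
    abs_o2 = c_abs_o2, abs_co2 = c_abs_co2,
    gas_in_o2 = c_gas_in_o2, gas_in_co2 = c_gas_in_co2,
    vent_o2 = c_vent_o2, vent_co2 = c_vent_co2,
    harvest_ct = c_harv_ct, harvest_o2 = c_harv_o2,
    harvested_g = harvested_total,
    ph_events = st$ph$n_events,
    ph_pi_samples = if (ctl$ph$mode == "pi_time") {
      length(seq(1L, nsteps, by = ts_steps[["ph"]]))
    } else {
      0L
    }
  )
  stock1 <- c(
    ct = sum(ct) * v_elem + ct_c * v_col,
    o2 = sum(o2) * v_elem + o2_c * v_col,
    cb = sum(cb) * v_elem + cb_c * v_col,
    gas_o2 = n_gas * y_o2, gas_co2 = n_gas * y_co2
  )
  out <- as.data.frame(logm[seq_len(ilog), , drop = FALSE])
  attr(out, "config") <- cfg
  attr(out, "counters") <- counters
  attr(out, "stock0") <- stock0
  attr(out, "stock1") <- stock1
  attr(out, "final_state") <- list(
    cb = cb, o2 = o2, ct = ct, cb_c = cb_c, o2_c = o2_c, ct_c = ct_c,
    y_o2 = y_o2, y_co2 = y_co2, T_loop = Tl, T_column = T_c
  )
  class(out) <- c("pbr_result", "data.frame")
  out
}

#' Conservation audits of a simulation result
#'
#' Post-hoc bookkeeping checks on any [run_simulation()] result: the change
#' of every stock must equal the accumulated sources and sinks logged during
#' the run. Carbon: dissolved injection + column absorption - net fixation
#' (gross - respiration, divided by the photosynthetic quotient) + harvest
#' make-up must match the change of the total-inorganic-carbon stock.
#' Oxygen: net photosynthetic O2 + column absorption + harvest must match
#' the dissolved stock change; the gas-phase holdup change must match
#' inflow - vent - transfer per species. Biomass: yield x gross O2 minus the
#' harvested mass.
#'
#' @param result A `pbr_result`.
#' @return A data.frame with one row per audit: stock change, the
#'   source/sink total, and their relative mismatch (scaled by the gross
#'   turnover of that stock).
#' @export
check_audits <- function(result) {
  cn <- attr(result, "counters")
  s0 <- attr(result, "stock0")
  s1 <- attr(result, "stock1")
  cfg <- attr(result, "config")
  kin <- attr(cfg, "objects")$kin
  pq <- kin$photosynthetic_quotient
  yld <- kin$yield_x_per_o2
  rows <- list(
    carbon_liquid = c(
      delta = s1[["ct"]] - s0[["ct"]],
      sources = cn$inj_dissolved + cn$abs_co2 -
        (cn$gross_o2 - cn$resp_o2) / pq + cn$harvest_ct
    ),
    oxygen_liquid = c(
      delta = s1[["o2"]] - s0[["o2"]],
      sources = (cn$gross_o2 - cn$resp_o2) + cn$abs_o2 + cn$harvest_o2
    ),
    oxygen_gas = c(
      delta = s1[["gas_o2"]] - s0[["gas_o2"]],
      sources = cn$gas_in_o2 - cn$vent_o2 - cn$abs_o2
    ),
    carbon_gas = c(
      delta = s1[["gas_co2"]] - s0[["gas_co2"]],
      sources = cn$gas_in_co2 - cn$vent_co2 - cn$abs_co2
    ),
    biomass = c(
      delta = s1[["cb"]] - s0[["cb"]],
      sources = yld * cn$gross_o2 - cn$harvested_g
    )
  )
  scales <- c(
    carbon_liquid = abs(cn$inj_dissolved) + abs(cn$abs_co2) +
      cn$gross_o2 / pq + abs(s0[["ct"]]),
    oxygen_liquid = cn$gross_o2 + abs(cn$abs_o2) + abs(s0[["o2"]]),
    oxygen_gas = cn$gas_in_o2 + abs(s0[["gas_o2"]]),
    carbon_gas = cn$gas_in_co2 + abs(cn$abs_co2) + abs(s0[["gas_co2"]]),
    biomass = yld * cn$gross_o2 + abs(s0[["cb"]])
  )
  out <- data.frame(
    audit = names(rows),
    delta = vapply(rows, `[[`, 0, "delta"),
    sources = vapply(rows, `[[`, 0, "sources"),
    row.names = NULL
  )
  out$rel_mismatch <- abs(out$delta - out$sources) / scales[out$audit]
  out
}
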