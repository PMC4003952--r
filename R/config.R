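#' Default simulation configuration
#'
#' Full nested configuration of the default plant: the 400 m x 0.09 m
#' fence-type loop with a 3.5 m x 0.4 m bubble column, 0.9 m/s culture
#' velocity, 80 L/min air sparging and up to 5 L/min of pure CO2, simulated
#' for one midsummer day at the Almeria latitude (36.8 N) under a clearness
#' index of 0.8. Kinetic, chemistry and controller defaults are calibration
#' constants of this simulator and are all overridable.
#'
#' @return Nested list of sections `simulation`, `environment`, `geometry`,
#'   `kinetics`, `chemistry`, `thermal`, `operation`, `control` (subsections
#'   `ph`, `flow`, `temp`) and `harvest`.
#' @export
pbr_defaults <- function() {
  list(
    simulation = list(
      duration_days = 1, dt_s = 1, start_day_of_year = 172,
      output_stride = 60, seed = 1
    ),
    environment = list(
      latitude = 36.8, longitude = -2.4, clearness_index = 0.8,
      ambient_mean_C = 22, ambient_amplitude_C = 6, ambient_peak_hour = 15
    ),
    geometry = list(
      tube_length_m = 400, tube_diameter_m = 0.09,
      column_height_m = 3.5, column_diameter_m = 0.4,
      n_elements = 50, liquid_fraction_column = 0.9,
      gas_fraction_column = 0.1
    ),
    kinetics = list(
      r_o2_max = 2.14e-7, i_half = 280, hill_n = 2,
      o2_inhibition_conc = 0.95, inhibition_exponent = 4,
      extinction_coeff = 0.06, yield_x_per_o2 = 26,
      photosynthetic_quotient = 1, respiration_rate = 2e-8,
      column_light_factor = 0
    ),
    chemistry = list(
      pk1 = 6.35, pk2 = 10.33, pkw = 14, alkalinity_mol_m3 = 13,
      henry_o2 = 1.3, henry_co2 = 34, kla_o2 = 0.02, kla_co2 = 0.021,
      co2_absorption_eff = 0.9
    ),
    thermal = list(
      u_wall_W_m2K = 15, absorptivity = 0.35, hx_UA_W_K = 500,
      n_thermal_volumes = NA, cooling_water_inlet_C = 20
    ),
    operation = list(
      velocity_m_s = 0.9, air_flow_L_min = 80, co2_max_flow_L_min = 5,
      air_y_o2 = 0.2095, air_y_co2 = 4.2e-4,
      pump_max_velocity_m_s = 1.8, cooling_max_flow_kg_s = 0.5,
      initial_biomass_g_m3 = 400, initial_ph = 8,
      initial_do2_mol_m3 = NA, # NA = air saturation
      initial_temperature_C = 22
    ),
    control = list(
      ph = list(
        mode = "manual", setpoint = 7.5, kp = -1.6, ti = 900, ts = 1800,
        delta = 0.025, hysteresis = 0.2, direction = 1,
        manual_value = 0, actuator_tau_s = 2
      ),
      flow = list(
        mode = "manual", setpoint = 0.9, kp = 1, ti = 20, ts = 1,
        delta = 0.02, hysteresis = 0.05, direction = -1,
        manual_value = 0.9, actuator_tau_s = 5
      ),
      temp = list(
        mode = "manual", setpoint = 25, kp = -0.2, ti = 900, ts = 60,
        delta = 0.25, hysteresis = 1, direction = 1,
        manual_value = 0, actuator_tau_s = 3
      )
    ),
    harvest = data.frame(time_h = numeric(0), fraction = numeric(0))
  )
}

# Deep-merge user overrides into the defaults, rejecting unknown keys.
merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(base)) {
      stop(sprintf("unknown configuration key '%s'", full), call. = FALSE)
    }
    if (is.list(base[[key]]) && !is.data.frame(base[[key]])) {
      if (!is.list(user[[key]])) {
        stop(sprintf("'%s' must be a section (list)", full), call. = FALSE)
      }
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Build and validate a simulation configuration
#'
#' Starts from [pbr_defaults()] and deep-merges any overrides given as
#' nested named lists; unknown keys are rejected with the offending
#' section.key named. All parameter objects are constructed once here so
#' invalid values fail fast.
#'
#' @param ... Named sections to override, e.g.
#'   `pbr_config(operation = list(velocity_m_s = 0.5))`.
#' @param manual_co2_schedule Optional data.frame `time_h`, `flow_L_min`
#'   stepping the manual CO2 flow (piecewise constant from each time on).
#' @return Validated nested list of class `pbr_config`.
#' @examples
#' cfg <- pbr_config(simulation = list(duration_days = 0.25))
#' @export
pbr_config <- function(..., manual_co2_schedule = NULL) {
  cfg <- merge_config(pbr_defaults(), list(...))
  if (!is.null(manual_co2_schedule)) {
    stopifnot(all(c("time_h", "flow_L_min") %in% names(manual_co2_schedule)))
    cfg$control$ph$schedule <- manual_co2_schedule[order(manual_co2_schedule$time_h), ]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  sim <- cfg$simulation
  if (sim$duration_days <= 0) stop("duration_days must be > 0", call. = FALSE)
  if (sim$dt_s <= 0) stop("dt_s must be > 0", call. = FALSE)
  if (sim$output_stride < 1) stop("output_stride must be >= 1", call. = FALSE)
  env <- cfg$environment
  if (env$latitude < -90 || env$latitude > 90) {
    stop("environment.latitude must be in [-90, 90]", call. = FALSE)
  }
  if (env$clearness_index < 0 || env$clearness_index > 1) {
    stop("environment.clearness_index must be in [0, 1]", call. = FALSE)
  }
  # construct parameter objects so their own validation runs
  geom <- do.call(pbr_geometry, cfg$geometry)
  kin <- do.call(kinetic_params, cfg$kinetics)
  chem <- do.call(chemistry_params, cfg$chemistry)
  th <- cfg$thermal
  thermal <- thermal_params(
    wall_conductance = th$u_wall_W_m2K, solar_absorptivity = th$absorptivity,
    hx_UA = th$hx_UA_W_K,
    n_thermal_volumes = if (is.na(th$n_thermal_volumes)) NULL else
      th$n_thermal_volumes
  )
  op <- cfg$operation
  if (op$velocity_m_s < 0 || op$air_flow_L_min < 0 ||
      op$co2_max_flow_L_min <= 0) {
    stop("operation flows must be non-negative (co2_max_flow > 0)",
      call. = FALSE
    )
  }
  for (loop in c("ph", "flow", "temp")) {
    cc <- cfg$control[[loop]]
    if (!cc$mode %in% c("manual", "onoff", "pi_time", "pi_event")) {
      stop(sprintf("control.%s.mode must be one of manual/onoff/pi_time/pi_event",
        loop
      ), call. = FALSE)
    }
    pi_config(cc$kp, cc$ti, cc$ts) # validates ti, ts
    if (cc$delta <= 0) {
      stop(sprintf("control.%s.delta must be > 0", loop), call. = FALSE)
    }
  }
  hv <- cfg$harvest
  if (nrow(hv) > 0) {
    if (any(hv$fraction < 0 | hv$fraction > 1)) {
      stop("harvest.fraction must be in [0, 1]", call. = FALSE)
    }
    cfg$harvest <- hv[order(hv$time_h), ]
  }
  attr(cfg, "objects") <- list(geom = geom, kin = kin, chem = chem,
                               thermal = thermal)
  class(cfg) <- c("pbr_config", "list")
  cfg
}

# ---- TOML-subset reader/writer ------------------------------------------
# Sections `[a]` / `[a.b]`, repeated tables `[[harvest]]`, `key = value`
# pairs, '#' comments, bare numbers, true/false, and quoted strings.

parse_toml_value <- function(txt, where) {
  txt <- trimws(txt)
  if (txt %in% c("true", "false")) {
    return(txt == "true")
  }
  if (grepl('^".*"$', txt)) {
    return(substr(txt, 2, nchar(txt) - 1))
  }
  val <- suppressWarnings(as.numeric(txt))
  if (is.na(val) && txt != "nan") {
    stop(sprintf("cannot parse value '%s' at %s", txt, where), call. = FALSE)
  }
  val
}

#' Read a simulation configuration file
#'
#' Parses a TOML-like configuration (sections `[geometry]`,
#' `[control.ph]`, ..., repeated `[[harvest]]` tables with `time_h` and
#' `fraction`, `key = value` lines, `#` comments) and returns the validated
#' configuration with defaults applied to everything not set. An empty file
#' yields the full default plant. Unknown keys are rejected.
#'
#' @param path Path to the configuration file.
#' @return A validated `pbr_config` object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  user <- list()
  harvest <- list()
  section <- character(0)
  in_harvest <- FALSE
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[\\[\\s*harvest\\s*\\]\\]$", ln)) {
      harvest[[length(harvest) + 1]] <- list()
      in_harvest <- TRUE
      next
    }
    if (grepl("^\\[[^\\[].*\\]$", ln)) {
      section <- strsplit(gsub("^\\[|\\]$", "", ln), ".", fixed = TRUE)[[1]]
      section <- trimws(section)
      in_harvest <- FALSE
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("config line %d is not a 'key = value' pair: '%s'", i, ln),
        call. = FALSE
      )
    }
    kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- parse_toml_value(kv[2], sprintf("line %d", i))
    if (in_harvest) {
      harvest[[length(harvest)]][[key]] <- val
    } else if (length(section) == 0) {
      stop(sprintf("config line %d: key '%s' outside any section", i, key),
        call. = FALSE
      )
    } else {
      user <- assign_path(user, c(section, key), val)
    }
  }
  args <- user
  if (length(harvest) > 0) {
    args$harvest <- data.frame(
      time_h = vapply(harvest, function(h) h$time_h %||% NA_real_, 0),
      fraction = vapply(harvest, function(h) h$fraction %||% NA_real_, 0)
    )
    if (anyNA(args$harvest)) {
      stop("each [[harvest]] table needs `time_h` and `fraction`",
        call. = FALSE
      )
    }
  }
  do.call(pbr_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Set a value at a nested path, creating intermediate lists as needed.
assign_path <- function(lst, path, val) {
  if (length(path) == 1) {
    lst[[path]] <- val
    return(lst)
  }
  if (is.null(lst[[path[1]]])) lst[[path[1]]] <- list()
  lst[[path[1]]] <- assign_path(lst[[path[1]]], path[-1], val)
  lst
}

#' Write a configuration file
#'
#' Serialises a configuration to the TOML-subset dialect read by
#' [read_config()]; `read_config(write_config(cfg, f))` round-trips.
#'
#' @param cfg A `pbr_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  fmt_val <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }
  out <- character(0)
  emit_section <- function(name, sec) {
    out <<- c(out, sprintf("[%s]", name))
    for (k in names(sec)) {
      v <- sec[[k]]
      if (length(v) == 1 && !is.na(v)) {
        out <<- c(out, sprintf("%s = %s", k, fmt_val(v)))
      }
    }
    out <<- c(out, "")
  }
  for (top in c("simulation", "environment", "geometry", "kinetics",
                "chemistry", "thermal", "operation")) {
    emit_section(top, cfg[[top]])
  }
  for (loop in names(cfg$control)) {
    sec <- cfg$control[[loop]]
    sec$schedule <- NULL
    emit_section(paste0("control.", loop), sec)
  }
  if (nrow(cfg$harvest) > 0) {
    for (r in seq_len(nrow(cfg$harvest))) {
      out <- c(out, "[[harvest]]",
        sprintf("time_h = %s", fmt_val(cfg$harvest$time_h[r])),
        sprintf("fraction = %s", fmt_val(cfg$harvest$fraction[r])), ""
      )
    }
  }
  writeLines(out, path)
  invisible(path)
}
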