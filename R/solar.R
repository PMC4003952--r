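#' Solar declination angle
#'
#' Cooper's formula for the declination of the sun as a function of the day
#' of the year, `23.45 * sin(2*pi*(284 + n)/365)` degrees.
#'
#' @param day_of_year Integer day of the year, 1..365.
#' @return Declination in degrees, in `[-23.45, 23.45]`.
#' @examples
#' solar_declination(172) # close to +23.45 at the June solstice
#' @export
solar_declination <- function(day_of_year) {
  if (any(day_of_year < 1 | day_of_year > 365)) {
    stop("`day_of_year` must be in [1, 365]", call. = FALSE)
  }
  23.45 * sin(2 * pi * (284 + day_of_year) / 365)
}

#' Cosine of the solar zenith angle
#'
#' Standard solar geometry on a horizontal surface: with hour angle
#' `omega = 15 * (solar_hour - 12)` degrees,
#' `cos(theta_z) = sin(phi) sin(delta) + cos(phi) cos(delta) cos(omega)`,
#' clipped to `[0, 1]` (the sun below the horizon gives 0).
#'
#' @param latitude Latitude in degrees north, `[-90, 90]`.
#' @param declination Solar declination in degrees.
#' @param solar_hour Local solar time in hours, `[0, 24]` (vectorised).
#' @return Dimensionless cosine of the zenith angle in `[0, 1]`.
#' @export
solar_cos_zenith <- function(latitude, declination, solar_hour) {
  if (any(latitude < -90 | latitude > 90)) {
    stop("`latitude` must be in [-90, 90]", call. = FALSE)
  }
  deg <- pi / 180
  omega <- 15 * (solar_hour - 12) * deg
  cz <- sin(latitude * deg) * sin(declination * deg) +
    cos(latitude * deg) * cos(declination * deg) * cos(omega)
  pmin(pmax(cz, 0), 1)
}

#' Extraterrestrial irradiance on a horizontal surface
#'
#' Top-of-atmosphere irradiance projected on the horizontal,
#' `G0 = Gsc * (1 + 0.033 cos(2*pi*day/365)) * cos(theta_z)` with the solar
#' constant `Gsc = 1367` W/m2.
#'
#' @param day_of_year Integer day of the year.
#' @param cos_zenith Cosine of the solar zenith angle, `[0, 1]`.
#' @return Irradiance in W/m2 (non-negative).
#' @export
solar_extraterrestrial <- function(day_of_year, cos_zenith) {
  if (any(cos_zenith < 0 | cos_zenith > 1)) {
    stop("`cos_zenith` must be in [0, 1]", call. = FALSE)
  }
  1367 * (1 + 0.033 * cos(2 * pi * day_of_year / 365)) * cos_zenith
}

#' Global horizontal irradiance from the clearness index
#'
#' The clearness index `kt` is the ratio of global surface irradiance to the
#' extraterrestrial irradiance; it is applied instantaneously per time step,
#' `G = kt * G0(day, cos_zenith)`. `kt` is fixed for a simulation run
#' (around 0.8 for the clearest sky, near 0 fully overcast).
#'
#' @param latitude Latitude in degrees north.
#' @param clearness_index Dimensionless `kt` in `[0, 1]`.
#' @param day_of_year Integer day of the year.
#' @param solar_hour Solar time in hours (vectorised).
#' @return Global horizontal irradiance in W/m2; zero at night.
#' @export
solar_global <- function(latitude, clearness_index, day_of_year, solar_hour) {
  if (any(clearness_index < 0 | clearness_index > 1)) {
    stop("`clearness_index` must be in [0, 1]", call. = FALSE)
  }
  dec <- solar_declination(day_of_year)
  cz <- solar_cos_zenith(latitude, dec, solar_hour)
  clearness_index * solar_extraterrestrial(day_of_year, cz)
}

#' Split global irradiance into direct and diffuse components
#'
#' Erbs piecewise-polynomial diffuse-fraction correlation:
#' for `kt <= 0.22`, `fd = 1 - 0.09 kt`; for `0.22 < kt <= 0.80`,
#' `fd = 0.9511 - 0.1604 kt + 4.388 kt^2 - 16.638 kt^3 + 12.336 kt^4`;
#' for `kt > 0.80`, `fd = 0.165`. Direct is the remainder, so
#' `direct + diffuse = global` exactly.
#'
#' @param global Global horizontal irradiance, W/m2 (vectorised).
#' @param clearness_index Clearness index used for the correlation.
#' @param cos_zenith Cosine of the zenith angle (used only to force both
#'   components to zero at night).
#' @return A list with numeric components `direct` and `diffuse` (W/m2).
#' @export
split_direct_diffuse <- function(global, clearness_index, cos_zenith) {
  if (any(global < 0)) stop("`global` must be >= 0", call. = FALSE)
  kt <- rep_len(clearness_index, length(global))
  fd <- ifelse(kt <= 0.22,
    1 - 0.09 * kt,
    ifelse(kt <= 0.80,
      0.9511 - 0.1604 * kt + 4.388 * kt^2 - 16.638 * kt^3 + 12.336 * kt^4,
      0.165
    )
  )
  fd <- pmin(pmax(fd, 0), 1)
  night <- rep_len(cos_zenith, length(global)) <= 0
  diffuse <- ifelse(night, 0, fd * global)
  direct <- ifelse(night, 0, global - diffuse)
  list(direct = direct, diffuse = diffuse)
}

#' Ambient temperature model
#'
#' Daily sinusoid `T(t) = mean + amplitude * cos(2*pi*(t - t_peak)/86400)`
#' with the peak at `peak_hour` solar time.
#'
#' @param time_s Time from simulation start (midnight solar time), seconds.
#' @param mean_C Daily mean temperature, degrees C.
#' @param amplitude_C Half peak-to-trough amplitude, K.
#' @param peak_hour Solar hour of the daily maximum (default 15:00).
#' @return Ambient temperature in degrees C.
#' @export
ambient_temperature <- function(time_s, mean_C = 22, amplitude_C = 6,
                                peak_hour = 15) {
  mean_C + amplitude_C * cos(2 * pi * (time_s - peak_hour * 3600) / 86400)
}

#' Generate a synthetic environment forcing series
#'
#' Builds the horizontal solar radiation series (global, direct, diffuse) and
#' ambient temperature for `n_days` starting at midnight solar time of
#' `start_day`. Solar time is used directly (no equation-of-time or longitude
#' correction); the declination is updated at each day boundary.
#'
#' @param latitude Degrees north.
#' @param longitude Degrees east (kept for provenance; not used by the solar
#'   time model).
#' @param clearness_index Clearness index `kt`, fixed over the run.
#' @param start_day Integer day of the year at the start.
#' @param n_days Simulation span in days (> 0).
#' @param step Time step of the series in seconds (> 0).
#' @param ambient_mean_C,ambient_amplitude_C,ambient_peak_hour Parameters of
#'   the sinusoidal ambient temperature model.
#' @return A data.frame of class `pbr_forcing` with columns `time_s`,
#'   `global_Wm2`, `direct_Wm2`, `diffuse_Wm2`, `ambient_C`.
#' @examples
#' f <- generate_forcing(36.8, -2.4, 0.8, start_day = 172, n_days = 1, step = 600)
#' @export
generate_forcing <- function(latitude, longitude = 0, clearness_index,
                             start_day, n_days, step,
                             ambient_mean_C = 22, ambient_amplitude_C = 6,
                             ambient_peak_hour = 15) {
  if (n_days <= 0) stop("`n_days` must be > 0", call. = FALSE)
  if (step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (longitude < -180 || longitude > 180) {
    stop("`longitude` must be in [-180, 180]", call. = FALSE)
  }
  time_s <- seq(0, n_days * 86400, by = step)
  day <- (start_day - 1 + time_s %/% 86400) %% 365 + 1
  solar_hour <- (time_s %% 86400) / 3600
  dec <- solar_declination(day)
  cz <- solar_cos_zenith(latitude, dec, solar_hour)
  g0 <- solar_extraterrestrial(day, cz)
  global <- clearness_index * g0
  sp <- split_direct_diffuse(global, clearness_index, cz)
  out <- data.frame(
    time_s = time_s,
    global_Wm2 = global,
    direct_Wm2 = sp$direct,
    diffuse_Wm2 = sp$diffuse,
    ambient_C = ambient_temperature(time_s, ambient_mean_C,
      ambient_amplitude_C, ambient_peak_hour
    )
  )
  class(out) <- c("pbr_forcing", "data.frame")
  out
}

#' Load a recorded forcing profile from CSV
#'
#' Reads a profile of measured horizontal global irradiance (and optionally
#' ambient temperature) standing in for data from previous real experiments.
#' Expected header: `time_s,global_Wm2` or `time_s,global_Wm2,ambient_C`;
#' comma separated, '.' decimal, lines starting with '#' are comments.
#' The direct/diffuse split is applied with the Erbs correlation using the
#' clearness index back-computed from the extraterrestrial irradiance at the
#' given location (capped at 1).
#'
#' @param path Path to the CSV file.
#' @param latitude Degrees north, used for the back-computed clearness index.
#' @param start_day Integer day of the year corresponding to `time_s = 0`.
#' @param ambient_mean_C,ambient_amplitude_C Fallback sinusoidal ambient model
#'   used when the file has no `ambient_C` column.
#' @return A `pbr_forcing` data.frame (see [generate_forcing()]).
#' @export
load_profile <- function(path, latitude = 36.8, start_day = 172,
                         ambient_mean_C = 22, ambient_amplitude_C = 6) {
  raw <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("time_s", "global_Wm2")
  if (!all(need %in% names(raw))) {
    stop("forcing CSV must have header `time_s,global_Wm2[,ambient_C]`",
      call. = FALSE
    )
  }
  for (cn in intersect(c("time_s", "global_Wm2", "ambient_C"), names(raw))) {
    if (!is.numeric(raw[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[cn]]))))[1]
      stop(sprintf("forcing CSV: unparsable value in column '%s', row %d",
        cn, if (is.na(bad)) 1L else bad
      ), call. = FALSE)
    }
  }
  if (anyNA(raw$time_s) || anyNA(raw$global_Wm2)) {
    stop(sprintf("forcing CSV: missing value at row %d",
      which(is.na(raw$time_s) | is.na(raw$global_Wm2))[1]
    ), call. = FALSE)
  }
  if (any(diff(raw$time_s) <= 0)) {
    stop(sprintf("forcing CSV: time not strictly increasing at data row %d",
      which(diff(raw$time_s) <= 0)[1] + 1L
    ), call. = FALSE)
  }
  if (any(raw$global_Wm2 < 0)) {
    stop(sprintf("forcing CSV: negative irradiance at row %d",
      which(raw$global_Wm2 < 0)[1]
    ), call. = FALSE)
  }
  time_s <- raw$time_s
  day <- (start_day - 1 + time_s %/% 86400) %% 365 + 1
  solar_hour <- (time_s %% 86400) / 3600
  cz <- solar_cos_zenith(latitude, solar_declination(day), solar_hour)
  g0 <- solar_extraterrestrial(day, cz)
  kt <- ifelse(g0 > 0, pmin(raw$global_Wm2 / g0, 1), 0)
  global <- ifelse(cz > 0, raw$global_Wm2, 0)
  sp <- split_direct_diffuse(global, kt, cz)
  ambient <- if ("ambient_C" %in% names(raw)) {
    raw$ambient_C
  } else {
    ambient_temperature(time_s, ambient_mean_C, ambient_amplitude_C)
  }
  out <- data.frame(
    time_s = time_s, global_Wm2 = global,
    direct_Wm2 = sp$direct, diffuse_Wm2 = sp$diffuse, ambient_C = ambient
  )
  class(out) <- c("pbr_forcing", "data.frame")
  out
}

# Linear interpolators onto the engine's time grid.
forcing_interpolator <- function(forcing) {
  list(
    global = stats::approxfun(forcing$time_s, forcing$global_Wm2, rule = 2),
    ambient = stats::approxfun(forcing$time_s, forcing$ambient_C, rule = 2)
  )
}
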