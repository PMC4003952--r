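#' Configuration for the manual CO2 step experiment
#'
#' The reference one-day experiment on the default plant: the CO2 injection
#' is handled by the pH loop, stepped manually from 0 to `flow_high` L/min
#' at `t_up` hours and down to `flow_low` L/min at `t_down` hours. With
#' `control = "pi_time"` or `"pi_event"` the same plant runs closed-loop at
#' `setpoint` instead (time-based or send-on-delta PI with the shipped
#' tuning).
#'
#' @param mode Control mode of the pH loop: one of "manual", "pi_time",
#'   "pi_event", "onoff".
#' @param flow_high,flow_low Manual CO2 flows, L/min.
#' @param t_up,t_down Step times, hours.
#' @param setpoint pH setpoint for the closed-loop modes.
#' @param ... Extra overrides passed to [pbr_config()].
#' @return A `pbr_config`.
#' @examples
#' cfg <- co2_step_scenario("manual")
#' @export
co2_step_scenario <- function(mode = c("manual", "pi_time", "pi_event",
                                       "onoff"),
                              flow_high = 2.16, flow_low = 0.72,
                              t_up = 4.15, t_down = 12.8,
                              setpoint = 7.5, ...) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    pbr_config(
      ...,
      manual_co2_schedule = data.frame(
        time_h = c(0, t_up, t_down),
        flow_L_min = c(0, flow_high, flow_low)
      )
    )
  } else {
    extra <- list(...)
    ph_over <- c(list(mode = mode, setpoint = setpoint),
                 extra$control$ph %||% list())
    extra$control$ph <- ph_over
    do.call(pbr_config, extra)
  }
}

#' Generate reproducible fixture files
#'
#' Small plain-text inputs for tests and demonstrations: `radiation` writes
#' a synthetic forcing profile CSV; `noisy_radiation` adds seeded Gaussian
#' noise (clipped at zero, night kept dark) emulating a recorded profile;
#' `step_test` writes a command-step input table for actuator/controller
#' identification exercises.
#'
#' @param kind One of "radiation", "noisy_radiation", "step_test".
#' @param path Output CSV path.
#' @param seed RNG seed (noise only).
#' @param latitude,clearness_index,start_day,n_days,step Forcing parameters.
#' @param noise_sd Noise standard deviation, W/m2.
#' @return `path`, invisibly.
#' @export
generate_fixtures <- function(kind = c("radiation", "noisy_radiation",
                                       "step_test"),
                              path, seed = 1, latitude = 36.8,
                              clearness_index = 0.8, start_day = 172,
                              n_days = 1, step = 300, noise_sd = 20) {
  kind <- match.arg(kind)
  if (kind == "step_test") {
    df <- data.frame(
      time_s = c(0, 600, 1200, 1800, 2400),
      command = c(0, 1, 1, 0.5, 0)
    )
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# step-test command profile", con)
    utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  f <- generate_forcing(latitude, 0, clearness_index, start_day, n_days, step)
  g <- f$global_Wm2
  if (kind == "noisy_radiation" && noise_sd > 0) {
    set.seed(seed)
    day <- g > 0
    g[day] <- pmax(g[day] + stats::rnorm(sum(day), 0, noise_sd), 0)
  }
  df <- data.frame(time_s = f$time_s, global_Wm2 = g, ambient_C = f$ambient_C)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# synthetic %s profile (seed %d)", kind, seed), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
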