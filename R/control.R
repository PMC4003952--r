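#' PI controller configuration
#'
#' Positional discrete PI with conditional-integration anti-windup,
#' `u = sat(kp e + (kp/ti) I)`; the integral `I` accumulates `e * dt` only
#' while the actuator is unsaturated (or the error drives it out of
#' saturation).
#'
#' @param kp Proportional gain, command units per unit error. The sign must
#'   match the plant: e.g. the pH loop uses a negative `kp` because opening
#'   the CO2 valve lowers pH (with error defined as setpoint - measurement).
#' @param ti Integral time, s (> 0).
#' @param ts Sampling period of the time-based mode, s (> 0).
#' @param u_min,u_max Command bounds.
#' @return List of class `pbr_pi_config`.
#' @export
pi_config <- function(kp, ti, ts, u_min = 0, u_max = 1) {
  if (ti <= 0 || ts <= 0) stop("need ti > 0 and ts > 0", call. = FALSE)
  if (u_min >= u_max) stop("need u_min < u_max", call. = FALSE)
  structure(list(kp = kp, ti = ti, ts = ts, u_min = u_min, u_max = u_max),
    class = "pbr_pi_config"
  )
}

#' Fresh PI controller state
#'
#' @param u0 Initial command (bumpless start value).
#' @return List with integrator `i`, held command `u`, held quantised error
#'   `e_q`, last transmitted send-on-delta level `level`, time of the last
#'   event `t_last`, and the event counter `n_events`.
#' @export
pi_state <- function(u0 = 0) {
  list(i = 0, u = u0, e_q = 0, level = 0L, t_last = 0, n_events = 0L)
}

# Shared PI law with conditional anti-windup. `dt_int` is the horizon over
# which the (held) previous error has acted since the last update.
pi_apply <- function(state, e, dt_int, e_prev, cfg) {
  i_new <- state$i + e_prev * dt_int
  u_raw <- cfg$kp * e + (cfg$kp / cfg$ti) * i_new
  if (u_raw > cfg$u_max || u_raw < cfg$u_min) {
    # integrate only if it pulls the command back toward the range
    u_noint <- cfg$kp * e + (cfg$kp / cfg$ti) * state$i
    if ((u_raw > cfg$u_max && u_noint > cfg$u_max && abs(u_raw) > abs(u_noint)) ||
        (u_raw < cfg$u_min && u_noint < cfg$u_min && abs(u_raw) > abs(u_noint))) {
      i_new <- state$i
      u_raw <- u_noint
    }
  }
  # hard integrator clamp: |kp/ti * I| can never exceed the command span
  i_cap <- (cfg$u_max - cfg$u_min) * cfg$ti / abs(cfg$kp)
  i_new <- min(max(i_new, -i_cap), i_cap)
  state$i <- i_new
  state$u <- min(max(cfg$kp * e + (cfg$kp / cfg$ti) * i_new, cfg$u_min),
    cfg$u_max
  )
  state
}

#' Time-based PI update
#'
#' Call once per sampling period `ts`; the command is held between calls.
#'
#' @param error Current error (setpoint - measurement).
#' @param state Controller state from [pi_state()].
#' @param cfg A [pi_config()] object.
#' @return Updated state; the command is `state$u`.
#' @export
pi_time_step <- function(error, state, cfg) {
  pi_apply(state, error, cfg$ts, error, cfg)
}

#' Symmetric send-on-delta sampler
#'
#' Quantises the measured signal on levels `setpoint + k * delta`; an event
#' fires only when the signal crosses the next level above or below the last
#' transmitted one, so a signal staying within one band generates no
#' communication.
#'
#' @param signal Current measurement.
#' @param setpoint Loop setpoint (the level grid is centred on it).
#' @param last_level Integer index of the last transmitted level.
#' @param delta Send-on-delta band width, units of the measurement (> 0).
#' @return List with `event` (logical) and `level` (integer index of the
#'   transmitted level; unchanged when no event fires).
#' @export
ssod_sample <- function(signal, setpoint, last_level, delta) {
  if (delta <= 0) stop("`delta` must be > 0", call. = FALSE)
  # nearest level actually crossed: floor/ceiling toward the signal
  x <- (signal - setpoint) / delta
  if (x >= last_level + 1) {
    list(event = TRUE, level = as.integer(floor(x)))
  } else if (x <= last_level - 1) {
    list(event = TRUE, level = as.integer(ceiling(x)))
  } else {
    list(event = FALSE, level = as.integer(last_level))
  }
}

#' Event-based PI update
#'
#' Send-on-delta control separates sensing from actuation: the measurement
#' is transmitted to the controller only at level-crossing events
#' ([ssod_sample()]), and the PI law runs on the held quantised error -- the
#' proportional term uses the last transmitted level and the integral
#' accrues it over elapsed time. Inside the central band the quantised
#' error is zero, so the command freezes and the loop is silent. Call this
#' every integration step with the currently held quantised error (updated
#' at events).
#'
#' @param quantised_error Error evaluated on the last transmitted level,
#'   `setpoint - (setpoint + level * delta) = -level * delta`.
#' @param dt Elapsed time since the previous call, s.
#' @param state Controller state ([pi_state()]).
#' @param cfg A [pi_config()] object.
#' @return Updated state with the command `u`.
#' @export
pi_event_update <- function(quantised_error, dt, state, cfg) {
  pi_apply(state, quantised_error, dt, quantised_error, cfg)
}

#' Relay (on/off) controller with deadband
#'
#' Switches on when `direction * (measured - setpoint) > hysteresis/2`, off
#' below `-hysteresis/2`, and holds the previous command inside the
#' deadband.
#'
#' @param measured Current measurement.
#' @param setpoint Loop setpoint.
#' @param previous Previous binary command (0 or 1).
#' @param hysteresis Total deadband width, measurement units (>= 0).
#' @param direction +1 if the actuator should open when the measurement is
#'   above the setpoint (e.g. CO2 valve vs pH), -1 otherwise.
#' @return Command 0 or 1.
#' @export
onoff_step <- function(measured, setpoint, previous, hysteresis = 0,
                       direction = 1) {
  if (hysteresis < 0) stop("`hysteresis` must be >= 0", call. = FALSE)
  e <- direction * (measured - setpoint)
  if (e > hysteresis / 2) 1 else if (e < -hysteresis / 2) 0 else previous
}

#' Identified first-order actuator model
#'
#' @param gain Physical output per unit command (e.g. L/min of CO2 for a
#'   fully open valve).
#' @param time_constant Actuator lag, s (0 = instantaneous).
#' @param out_min,out_max Physical output limits.
#' @return List of class `pbr_actuator`.
#' @export
actuator_model <- function(gain, time_constant = 0, out_min = 0,
                           out_max = Inf) {
  if (time_constant < 0) stop("`time_constant` must be >= 0", call. = FALSE)
  structure(
    list(gain = gain, time_constant = time_constant,
         out_min = out_min, out_max = out_max),
    class = "pbr_actuator"
  )
}

#' Advance an actuator by one step
#'
#' First-order lag `dx/dt = (gain * command - x) / tau` advanced with the
#' exact exponential update (so any `dt` is stable), clipped to the physical
#' limits; `tau = 0` passes the command through instantaneously.
#'
#' @param command Controller command (clipped to `[0, 1]` upstream).
#' @param x Current physical output.
#' @param model An [actuator_model()] object.
#' @param dt Time step, s (> 0).
#' @return New physical output.
#' @export
actuator_step <- function(command, x, model, dt) {
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  target <- model$gain * command
  x_new <- if (model$time_constant == 0) {
    target
  } else {
    target + (x - target) * exp(-dt / model$time_constant)
  }
  min(max(x_new, model$out_min), model$out_max)
}
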