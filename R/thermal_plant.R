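# Lumped-capacitance thermal model of the laser-heated amplification chamber.
#
# The chamber sits on a micro graphite film with very high in-plane
# conductivity, so internal gradients are neglected and the chamber is a
# single well-mixed thermal node:
#
#   C dT/dt = P * 1[laser on] - k * (T - T_amb)
#
# with C the lumped heat capacity (J/degC), k the loss coefficient (W/degC)
# and P the absorbed laser power (W) while the beam is on.

#' Thermal plant parameters
#'
#' @param ambient_temp ambient temperature, degC.
#' @param heat_capacity lumped heat capacity of the chamber, J/degC.
#' @param loss_coeff heat-loss coefficient to ambient, W/degC.
#' @param absorbed_power absorbed laser power while the beam is on, W.
#' @param duty_steady_70 duty ratio at which the steady state is 70 degC
#'   (calibration anchor).
#' @return an object of class `plant_params`.
#' @export
plant_params <- function(ambient_temp = 25, heat_capacity = 60,
                         loss_coeff = 1, absorbed_power = 90,
                         duty_steady_70 = 0.5) {
  check_number(ambient_temp, "ambient_temp")
  check_number(heat_capacity, "heat_capacity", lower = 0, strict_lower = TRUE)
  check_number(loss_coeff, "loss_coeff", lower = 0, strict_lower = TRUE)
  check_number(absorbed_power, "absorbed_power", lower = 0, strict_lower = TRUE)
  check_number(duty_steady_70, "duty_steady_70", lower = 0, upper = 1,
               strict_lower = TRUE)
  structure(
    list(ambient_temp = ambient_temp, heat_capacity = heat_capacity,
         loss_coeff = loss_coeff, absorbed_power = absorbed_power,
         duty_steady_70 = duty_steady_70),
    class = "plant_params"
  )
}

#' @export
print.plant_params <- function(x, ...) {
  cat("Thermal plant (lumped single node)\n")
  cat(sprintf("  ambient        : %.2f degC\n", x$ambient_temp))
  cat(sprintf("  heat capacity  : %.3f J/degC\n", x$heat_capacity))
  cat(sprintf("  loss coeff     : %.4f W/degC\n", x$loss_coeff))
  cat(sprintf("  absorbed power : %.3f W\n", x$absorbed_power))
  cat(sprintf("  time constant  : %.1f s\n", x$heat_capacity / x$loss_coeff))
  cat(sprintf("  steady state at duty 1: %.2f degC\n",
              x$ambient_temp + x$absorbed_power / x$loss_coeff))
  invisible(x)
}

#' Thermal state of the chamber
#'
#' @param time simulation time, s.
#' @param temperature chamber temperature, degC.
#' @return an object of class `thermal_state`.
#' @export
thermal_state <- function(time = 0, temperature = 25) {
  check_number(time, "time")
  check_number(temperature, "temperature")
  structure(list(time = time, temperature = temperature),
            class = "thermal_state")
}

# One classical RK4 step of the (piecewise-linear) node ODE.
rk4_step <- function(temp, params, power, h) {
  f <- function(t_val) {
    (power - params$loss_coeff * (t_val - params$ambient_temp)) /
      params$heat_capacity
  }
  k1 <- f(temp)
  k2 <- f(temp + h / 2 * k1)
  k3 <- f(temp + h / 2 * k2)
  k4 <- f(temp + h * k3)
  temp + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Advance the thermal plant by one interval
#'
#' Integrates `dT/dt = (P * laser_on - k (T - T_amb)) / C` over `dt` with a
#' fixed-step fourth-order Runge-Kutta scheme. The interval is subdivided so
#' that no internal step exceeds `max_step`; the integration error is far
#' below sensor noise (see the closed-form oracle tests).
#'
#' @param state a [thermal_state()].
#' @param params a [plant_params()].
#' @param laser_on logical, whether the laser is on during the interval.
#' @param dt interval length, s (> 0).
#' @param max_step maximum internal integration step, s.
#' @return the advanced `thermal_state`.
#' @export
step_plant <- function(state, params, laser_on, dt, max_step = 0.05) {
  stopifnot(inherits(state, "thermal_state"), inherits(params, "plant_params"))
  check_flag(laser_on, "laser_on")
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(max_step, "max_step", lower = 0, strict_lower = TRUE)
  if (!is.finite(state$temperature)) stop_invalid("non-finite temperature")
  power <- if (laser_on) params$absorbed_power else 0
  n_sub <- max(1L, ceiling(dt / max_step))
  h <- dt / n_sub
  temp <- state$temperature
  for (i in seq_len(n_sub)) temp <- rk4_step(temp, params, power, h)
  thermal_state(time = state$time + dt, temperature = temp)
}

#' Closed-form chamber temperature under constant laser power
#'
#' Analytic solution of the linear node ODE, used as the independent oracle
#' for the fixed-step integrator:
#' `T(t) = T_inf + (T0 - T_inf) exp(-k t / C)` with
#' `T_inf = T_amb + P_on / k`.
#'
#' @param t time since `t0`, s (vectorised).
#' @param t0_temp temperature at `t = 0`, degC.
#' @param params a [plant_params()].
#' @param laser_on logical, constant laser state.
#' @return temperatures, degC.
#' @export
plant_closed_form <- function(t, t0_temp, params, laser_on) {
  stopifnot(inherits(params, "plant_params"))
  power <- if (laser_on) params$absorbed_power else 0
  t_inf <- params$ambient_temp + power / params$loss_coeff
  t_inf + (t0_temp - t_inf) *
    exp(-params$loss_coeff * t / params$heat_capacity)
}

#' Simulate the plant under fixed-duty PWM laser drive
#'
#' Each PWM period starts with the laser on for `duty * pwm_period` seconds
#' and off for the remainder. Temperature ripple within the period is
#' retained; the trace reports the instantaneous node temperature on the
#' integration grid.
#'
#' @param params a [plant_params()].
#' @param duty duty ratio in \[0, 1\].
#' @param duration total simulated time, s.
#' @param pwm_period PWM period, s (default 1 s: 0.5 s on / 0.5 s off at
#'   duty 0.5).
#' @param dt integration/reporting step, s.
#' @param state0 initial [thermal_state()]; defaults to ambient at t = 0.
#' @return a data.frame with columns `time_s`, `duty`, `laser_on`,
#'   `temperature_C`.
#' @export
simulate_pwm <- function(params, duty, duration, pwm_period = 1,
                         dt = 0.05, state0 = NULL) {
  stopifnot(inherits(params, "plant_params"))
  check_number(duty, "duty", lower = 0, upper = 1)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(pwm_period, "pwm_period", lower = 0, strict_lower = TRUE)
  if (is.null(state0)) state0 <- thermal_state(0, params$ambient_temp)
  stopifnot(inherits(state0, "thermal_state"))

  n <- ceiling(duration / dt)
  time_s <- state0$time + seq_len(n) * dt
  temperature <- numeric(n)
  laser <- logical(n)
  state <- state0
  on_time <- duty * pwm_period
  for (i in seq_len(n)) {
    # laser state decided by position of the sub-interval within its period
    phase <- ((state$time - state0$time) %% pwm_period)
    laser_on <- phase < on_time - 1e-12
    state <- step_plant(state, params, laser_on, dt, max_step = dt)
    temperature[i] <- state$temperature
    laser[i] <- laser_on
  }
  data.frame(time_s = time_s, duty = duty, laser_on = laser,
             temperature_C = temperature)
}

#' Calibrate the thermal plant from its steady-state anchor
#'
#' The instrument's auto-calibration heats at a 1:1 PWM duty ratio until the
#' chamber plateaus; the plateau is the 70 degC anchor. Given ambient
#' temperature, the steady state reached at duty 0.5 and the exponential
#' time constant, this solves the steady-state balance
#' `P * d = k * (T_ss - T_amb)` at `d = 0.5` together with `tau = C / k`.
#' The absolute scale of (P, k, C) is not identifiable from temperature
#' alone, so `heat_capacity` fixes it.
#'
#' @param t_amb ambient temperature, degC.
#' @param t_steady_at_half_duty time-averaged steady state at duty 0.5, degC.
#' @param time_constant exponential time constant `C / k`, s.
#' @param heat_capacity lumped heat capacity, J/degC (scale choice).
#' @return a calibrated [plant_params()].
#' @export
calibrate_plant <- function(t_amb = 25, t_steady_at_half_duty = 70,
                            time_constant = 60, heat_capacity = 60) {
  check_number(t_amb, "t_amb")
  check_number(t_steady_at_half_duty, "t_steady_at_half_duty")
  check_number(time_constant, "time_constant", lower = 0, strict_lower = TRUE)
  check_number(heat_capacity, "heat_capacity", lower = 0, strict_lower = TRUE)
  if (t_steady_at_half_duty <= t_amb) {
    stop_invalid("calibration error: steady-state temperature (",
                 t_steady_at_half_duty, ") must exceed ambient (", t_amb,
                 "); no positive laser power can satisfy the anchor")
  }
  k <- heat_capacity / time_constant
  p <- k * (t_steady_at_half_duty - t_amb) / 0.5
  plant_params(ambient_temp = t_amb, heat_capacity = heat_capacity,
               loss_coeff = k, absorbed_power = p, duty_steady_70 = 0.5)
}
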