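# Auto-calibrated PD/PWM temperature controller.
#
# Two-phase procedure mirroring the instrument firmware:
#   1. calibration: heat at a 1:1 PWM duty ratio (0.5 s on / 0.5 s off)
#      until the TOCS intensity no longer changes; the plateau mean is the
#      maximum intensity i_max (it corresponds to 70 degC).
#   2. hold: target intensity = 50% of i_max (which the heating-branch
#      curve places at 60 degC); proportional-derivative control of the
#      PWM duty ratio for the 40-min LAMP hold.
#
# The control loop senses and regulates on the heating branch of the TOCS
# curve: the calibration curve the instrument constructs is the heating
# branch, and the setpoint is approached by heating. The cooling branch is
# exercised by the sensor module's hysteresis tests and post-run cooldown.

#' Controller configuration
#'
#' @param kp proportional gain, duty per unit normalized-intensity error.
#' @param kd derivative gain, duty * s per unit normalized-intensity error.
#' @param pwm_period PWM period, s; one duty decision per period.
#' @param duty_min,duty_max actuation limits.
#' @param hold_duration PD hold length, s (default 2400 s = 40 min).
#' @param plateau_window plateau-detection window, s.
#' @param plateau_epsilon plateau threshold on the change between successive
#'   window means, normalized-intensity units.
#' @param calibration_timeout maximum calibration time, s.
#' @param target_fraction fraction of maximum intensity used as the target.
#' @param duty_quantum duty quantization of the laser driver.
#' @param noise_sd camera noise passed to [observe()], normalized units.
#' @param form `"velocity"` (incremental, default) or `"positional"` PD law.
#' @param duty_bias operating-point bias of the positional form.
#' @param dt plant integration step, s.
#' @param settle_band,settle_window transient-end rule of
#'   [steady_state_mse()]: |T - setpoint| <= band sustained for window s.
#' @return an object of class `controller_config`.
#' @export
controller_config <- function(kp = 2, kd = 8, pwm_period = 1,
                              duty_min = 0, duty_max = 1,
                              hold_duration = 2400,
                              plateau_window = 60, plateau_epsilon = 0.005,
                              calibration_timeout = 600,
                              target_fraction = 0.5, duty_quantum = 0.01,
                              noise_sd = 0.01,
                              form = c("velocity", "positional"),
                              duty_bias = 0.5, dt = 0.05,
                              settle_band = 0.5, settle_window = 60) {
  form <- match.arg(form)
  check_number(kp, "kp", lower = 0)
  check_number(kd, "kd", lower = 0)
  check_number(pwm_period, "pwm_period", lower = 0, strict_lower = TRUE)
  check_number(duty_min, "duty_min", lower = 0, upper = 1)
  check_number(duty_max, "duty_max", lower = duty_min, upper = 1,
               strict_lower = TRUE)
  check_number(hold_duration, "hold_duration", lower = 0, strict_lower = TRUE)
  check_number(plateau_window, "plateau_window", lower = pwm_period)
  check_number(plateau_epsilon, "plateau_epsilon", lower = 0)
  check_number(calibration_timeout, "calibration_timeout", lower = 0,
               strict_lower = TRUE)
  check_number(target_fraction, "target_fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(duty_quantum, "duty_quantum", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  structure(
    list(kp = kp, kd = kd, pwm_period = pwm_period,
         duty_min = duty_min, duty_max = duty_max,
         hold_duration = hold_duration,
         plateau_window = plateau_window, plateau_epsilon = plateau_epsilon,
         calibration_timeout = calibration_timeout,
         target_fraction = target_fraction, duty_quantum = duty_quantum,
         noise_sd = noise_sd, form = form, duty_bias = duty_bias, dt = dt,
         settle_band = settle_band, settle_window = settle_window),
    class = "controller_config"
  )
}

# Integrate one PWM period: laser on for duty * period, then off.
simulate_period <- function(state, params, duty, cfg) {
  on_time <- duty * cfg$pwm_period
  off_time <- cfg$pwm_period - on_time
  if (on_time > 0) {
    state <- step_plant(state, params, TRUE, on_time, max_step = cfg$dt)
  }
  if (off_time > 0) {
    state <- step_plant(state, params, FALSE, off_time, max_step = cfg$dt)
  }
  state
}

# Invert a measured intensity to temperature, clamping into the invertible
# open interval first (noise can push readings onto/past the asymptotes).
estimate_temperature <- function(intensity, tocs, branch = "heating") {
  span <- tocs$i_max - tocs$i_min
  eps <- 1e-6 * span
  clamped <- pmin(pmax(intensity, tocs$i_min + eps), tocs$i_max - eps)
  temperature_from_intensity(clamped, branch, tocs)
}

new_trace_rows <- function(n) {
  data.frame(time_s = numeric(n), phase = character(n), duty = numeric(n),
             true_temperature_C = numeric(n),
             measured_intensity = numeric(n),
             estimated_temperature_C = numeric(n),
             branch = character(n), stringsAsFactors = FALSE)
}

#' Run the 1:1-duty calibration phase
#'
#' Heats at duty 0.5 and watches the measured intensity: once the change
#' between the means of two successive `plateau_window` windows falls below
#' `plateau_epsilon`, two confirmation windows are appended (letting the
#' exponential tail die out) and the mean over the final window is returned
#' as the maximum intensity `i_max`.
#'
#' @param plant a [plant_params()].
#' @param tocs a [tocs_model()].
#' @param cfg a [controller_config()].
#' @param rng_seed optional seed for the camera noise.
#' @param state0 initial [thermal_state()]; defaults to ambient.
#' @return a list with `i_max`, the trace segment (`trace`), the final
#'   plant `state`, and `calibration_time` in s.
#' @export
run_calibration_phase <- function(plant, tocs, cfg = controller_config(),
                                  rng_seed = NULL, state0 = NULL) {
  stopifnot(inherits(plant, "plant_params"), inherits(tocs, "tocs_model"),
            inherits(cfg, "controller_config"))
  if (is.null(state0)) state0 <- thermal_state(0, plant$ambient_temp)
  with_seed(rng_seed, {
    w <- max(1L, round(cfg$plateau_window / cfg$pwm_period))
    max_ticks <- ceiling(cfg$calibration_timeout / cfg$pwm_period)
    duty <- plant$duty_steady_70
    trace <- new_trace_rows(max_ticks)
    intens <- numeric(max_ticks)
    state <- state0
    plateau_at <- NA_integer_
    n <- 0L
    for (k in seq_len(max_ticks)) {
      state <- simulate_period(state, plant, duty, cfg)
      meas <- observe(state$temperature, "heating", tocs,
                      noise_sd = cfg$noise_sd,
                      time = state$time)$normalized_intensity
      n <- k
      intens[k] <- meas
      trace[k, ] <- list(state$time, "calibration", duty, state$temperature,
                         meas, estimate_temperature(meas, tocs), "heating")
      if (is.na(plateau_at) && k >= 2L * w) {
        m1 <- mean(intens[(k - w + 1L):k])
        m0 <- mean(intens[(k - 2L * w + 1L):(k - w)])
        if (abs(m1 - m0) < cfg$plateau_epsilon) plateau_at <- k
      }
      if (!is.na(plateau_at) && k >= plateau_at + 2L * w) break
    }
    if (is.na(plateau_at) || n < plateau_at + 2L * w) {
      stop(structure(
        class = c("lodlamp_calibration_timeout", "error", "condition"),
        list(message = sprintf(
          "calibration timeout: intensity plateau (epsilon %.4g over %gs) not reached within %gs",
          cfg$plateau_epsilon, cfg$plateau_window, cfg$calibration_timeout),
          call = sys.call(-1))))
    }
    list(i_max = mean(intens[(n - w + 1L):n]), trace = trace[seq_len(n), ],
         state = state, calibration_time = state$time - state0$time)
  })
}

#' Intensity target from the calibrated maximum
#'
#' @param i_max maximum normalized intensity found by calibration (> 0).
#' @param cfg a [controller_config()] providing `target_fraction`.
#' @return target normalized intensity, `target_fraction * i_max`.
#' @export
compute_target <- function(i_max, cfg = controller_config()) {
  stopifnot(inherits(cfg, "controller_config"))
  check_number(i_max, "i_max", lower = 0, strict_lower = TRUE)
  cfg$target_fraction * i_max
}

#' One PD duty update
#'
#' Velocity form (default): `duty = prev_duty + kp * e + kd * (e - e_prev) / dt`;
#' positional form replaces `prev_duty` by the fixed `duty_bias`. The result
#' is quantized to `duty_quantum` and clipped to `[duty_min, duty_max]`
#' (clipping is defined behaviour, not an error).
#'
#' @param error current intensity error, target minus measured.
#' @param prev_error previous intensity error.
#' @param dt time since the previous update, s.
#' @param cfg a [controller_config()].
#' @param prev_duty duty applied during the previous period.
#' @return the new duty ratio.
#' @export
pd_step <- function(error, prev_error, dt, cfg = controller_config(),
                    prev_duty = 0.5) {
  stopifnot(inherits(cfg, "controller_config"))
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  base <- if (cfg$form == "velocity") prev_duty else cfg$duty_bias
  raw <- base + cfg$kp * error + cfg$kd * (error - prev_error) / dt
  if (cfg$duty_quantum > 0) raw <- round(raw / cfg$duty_quantum) * cfg$duty_quantum
  min(max(raw, cfg$duty_min), cfg$duty_max)
}

#' Run the PD hold phase
#'
#' Executes `hold_duration` seconds of closed-loop PD control at one duty
#' decision per PWM period, starting from a completed calibration
#' (`i_max` known).
#'
#' @inheritParams run_calibration_phase
#' @param i_max calibrated maximum intensity.
#' @param start_duty duty carried over from calibration.
#' @return a `ControlTrace` data.frame (`time_s`, `phase`, `duty`,
#'   `true_temperature_C`, `measured_intensity`, `estimated_temperature_C`,
#'   `branch`).
#' @export
run_closed_loop <- function(plant, tocs, cfg = controller_config(),
                            rng_seed = NULL, i_max = NULL, state0 = NULL,
                            start_duty = NULL) {
  stopifnot(inherits(plant, "plant_params"), inherits(tocs, "tocs_model"),
            inherits(cfg, "controller_config"))
  if (is.null(i_max)) stop_invalid("i_max is required: run calibration first")
  if (is.null(state0)) state0 <- thermal_state(0, plant$ambient_temp)
  if (is.null(start_duty)) start_duty <- plant$duty_steady_70
  with_seed(rng_seed, {
    target <- compute_target(i_max, cfg)
    n_ticks <- ceiling(cfg$hold_duration / cfg$pwm_period)
    trace <- new_trace_rows(n_ticks)
    state <- state0
    duty <- start_duty
    prev_error <- NULL
    for (k in seq_len(n_ticks)) {
      state <- simulate_period(state, plant, duty, cfg)
      if (!is.finite(state$temperature)) {
        stop(structure(
          class = c("lodlamp_simulation_error", "error", "condition"),
          list(message = "plant divergence: non-finite temperature",
               call = sys.call(-1))))
      }
      meas <- observe(state$temperature, "heating", tocs,
                      noise_sd = cfg$noise_sd,
                      time = state$time)$normalized_intensity
      trace[k, ] <- list(state$time, "hold", duty, state$temperature,
                         meas, estimate_temperature(meas, tocs), "heating")
      error <- target - meas
      if (is.null(prev_error)) prev_error <- error
      duty <- pd_step(error, prev_error, cfg$pwm_period, cfg, duty)
      prev_error <- error
    }
    trace
  })
}

#' Run the full two-phase control procedure
#'
#' Calibration followed by the PD hold; convenience wrapper used by the
#' disc sequencer and the end-to-end report.
#'
#' @inheritParams run_calibration_phase
#' @param hold_duration optional override of `cfg$hold_duration`, s.
#' @param total_duration alternative to `hold_duration`: total time budget
#'   for calibration plus hold; the hold fills what calibration leaves.
#' @return a list: `trace` (both phases), `i_max`, `target`,
#'   `calibration_time`.
#' @export
run_control <- function(plant, tocs, cfg = controller_config(),
                        rng_seed = NULL, hold_duration = NULL,
                        total_duration = NULL) {
  with_seed(rng_seed, {
    cal <- run_calibration_phase(plant, tocs, cfg)
    if (!is.null(total_duration)) {
      check_number(total_duration, "total_duration", lower = 0,
                   strict_lower = TRUE)
      hold_duration <- total_duration - cal$calibration_time
      if (hold_duration <= 0) {
        stop_invalid(sprintf(
          "calibration (%.0fs) exceeds the total time budget (%.0fs)",
          cal$calibration_time, total_duration))
      }
    }
    if (!is.null(hold_duration)) {
      check_number(hold_duration, "hold_duration", lower = 0,
                   strict_lower = TRUE)
      cfg$hold_duration <- hold_duration
    }
    hold <- run_closed_loop(plant, tocs, cfg, i_max = cal$i_max,
                            state0 = cal$state,
                            start_duty = plant$duty_steady_70)
    list(trace = rbind(cal$trace, hold), i_max = cal$i_max,
         target = compute_target(cal$i_max, cfg),
         calibration_time = cal$calibration_time)
  })
}

#' Steady-state mean squared temperature error of a control trace
#'
#' Finds the end of the transient as the first time the estimated
#' temperature stays within `band` of the setpoint for `sustain_window`
#' seconds, then averages the squared temperature error over the remaining
#' hold phase.
#'
#' @param trace a `ControlTrace` data.frame containing a hold phase.
#' @param setpoint temperature setpoint, degC (default 60).
#' @param band settling band, degC.
#' @param sustain_window time the trace must stay in band, s.
#' @return a list with `mse` (degC^2), `transient_end_s`, and `n` (ticks
#'   averaged).
#' @export
steady_state_mse <- function(trace, setpoint = 60, band = 0.5,
                             sustain_window = 60) {
  stopifnot(is.data.frame(trace))
  hold <- trace[trace$phase == "hold", , drop = FALSE]
  if (nrow(hold) == 0L) stop_invalid("trace contains no hold phase")
  err <- hold$estimated_temperature_C - setpoint
  tick <- if (nrow(hold) > 1L) stats::median(diff(hold$time_s)) else 1
  w <- max(1L, round(sustain_window / tick))
  in_band <- abs(err) <= band
  # first index whose forward window of w ticks is entirely in band
  run_ok <- stats::filter(as.numeric(in_band), rep(1, w), sides = 1)
  start <- which(run_ok == w)[1] - w + 1L
  if (is.na(start)) {
    stop(structure(
      class = c("lodlamp_not_settled", "error", "condition"),
      list(message = sprintf(
        "transient never ended: |T - %g| <= %g degC never sustained for %gs",
        setpoint, band, sustain_window), call = sys.call(-1))))
  }
  idx <- start:nrow(hold)
  list(mse = mean(err[idx]^2), transient_end_s = hold$time_s[start],
       n = length(idx))
}
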