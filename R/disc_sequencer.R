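# Disc driving sequence: the ordered valve/spin/heating protocol of the
# centrifugal disc, validated and executed as a simple state machine.

PROTOCOL_OPERATIONS <- c("sample_injection", "spin", "laser_valve_LB",
                         "laser_valve_EVA", "laser_heating")

#' Construct one protocol step
#'
#' @param index 1-based step index.
#' @param operation one of `"sample_injection"`, `"spin"`,
#'   `"laser_valve_LB"`, `"laser_valve_EVA"`, `"laser_heating"`.
#' @param spin_speed spindle speed in rpm, or `NA` for non-spin steps.
#' @param duration step duration in s, or `NA` (sample injection).
#' @param description free-text operation description.
#' @return a one-row data.frame of class `protocol_step`.
#' @export
protocol_step <- function(index, operation, spin_speed = NA_real_,
                          duration = NA_real_, description = "") {
  check_number(index, "index", lower = 1)
  if (!operation %in% PROTOCOL_OPERATIONS) {
    stop_invalid("unknown operation '", operation, "'")
  }
  out <- data.frame(index = as.integer(index), operation = operation,
                    spin_speed = as.numeric(spin_speed),
                    duration = as.numeric(duration),
                    description = description, stringsAsFactors = FALSE)
  class(out) <- c("protocol_step", class(out))
  out
}

#' The default disc driving sequence
#'
#' The seven-step sequence of the instrument: inject, move the sample into
#' the channel, open the laser-burst (LB) valve, spin residuals to waste,
#' melt the EVA sealing valve, spin the melted valve radially outward to
#' block the chamber, then laser-heat the amplification chamber at the
#' controller-adjusted duty ratio for 40 min.
#'
#' @return a data.frame of 7 protocol steps.
#' @export
default_protocol <- function() {
  rbind(
    protocol_step(1, "sample_injection", NA, NA, "Sample injection"),
    protocol_step(2, "spin", 3000, 30, "Spin out to move samples in the channel"),
    protocol_step(3, "laser_valve_LB", NA, 10, "Irradiate laser to LB valve"),
    protocol_step(4, "spin", 3000, 10, "Spin out the residual to waste chamber"),
    protocol_step(5, "laser_valve_EVA", NA, 60, "Irradiate laser to melting EVA valve"),
    protocol_step(6, "spin", 10000, 60, "Spin out to push the melted EVA valve in radial way"),
    protocol_step(7, "laser_heating", NA, 2400,
                  "Irradiate laser to amplification chamber in adjusted duty ratio")
  )
}

#' Validate a protocol
#'
#' Checks per-step invariants (positive spin speeds and durations, strictly
#' increasing indices) plus ordering constraints of the disc workflow: the
#' LB valve must open before the metering spin that pushes residuals to
#' waste, and EVA sealing (melt, then a high-rpm spin) must be complete
#' before chamber heating starts, otherwise the chamber would evaporate.
#' Violations are reported, not raised.
#'
#' @param steps a protocol data.frame as returned by [default_protocol()].
#' @return a list with `valid` (logical) and `violations`
#'   (character vector).
#' @export
validate_protocol <- function(steps) {
  stopifnot(is.data.frame(steps))
  v <- character(0)
  if (nrow(steps) == 0L) {
    return(list(valid = TRUE, violations = character(0)))
  }
  bad_op <- !steps$operation %in% PROTOCOL_OPERATIONS
  if (any(bad_op)) {
    v <- c(v, sprintf("step %d: unknown operation '%s'",
                      steps$index[bad_op], steps$operation[bad_op]))
  }
  if (any(diff(steps$index) <= 0)) {
    v <- c(v, "step indices are not strictly increasing")
  }
  spin <- steps$operation == "spin"
  bad_spin <- spin & (is.na(steps$spin_speed) | steps$spin_speed <= 0)
  if (any(bad_spin)) {
    v <- c(v, sprintf("step %d: spin step requires spin_speed > 0",
                      steps$index[bad_spin]))
  }
  laser <- steps$operation %in% c("laser_valve_LB", "laser_valve_EVA",
                                  "laser_heating")
  bad_laser <- laser & (is.na(steps$duration) | steps$duration <= 0)
  if (any(bad_laser)) {
    v <- c(v, sprintf("step %d: laser step requires duration > 0",
                      steps$index[bad_laser]))
  }
  pos <- function(op) which(steps$operation == op)[1]
  i_lb <- pos("laser_valve_LB"); i_eva <- pos("laser_valve_EVA")
  i_heat <- pos("laser_heating")
  if (!is.na(i_lb)) {
    later_spin <- which(spin & seq_len(nrow(steps)) > i_lb)
    if (length(later_spin) == 0L) {
      v <- c(v, "LB valve opening is not followed by a metering spin")
    }
  }
  if (!is.na(i_heat)) {
    if (is.na(i_eva) || i_eva > i_heat) {
      v <- c(v, "EVA valve melting must precede chamber heating")
    } else {
      seal_spin <- which(spin & !is.na(steps$spin_speed) &
                           steps$spin_speed >= 5000)
      seal_spin <- seal_spin[seal_spin > i_eva & seal_spin < i_heat]
      if (length(seal_spin) == 0L) {
        v <- c(v, paste0("EVA sealing requires a high-rpm spin between ",
                         "valve melting and chamber heating"))
      }
    }
  }
  list(valid = length(v) == 0L, violations = v)
}

#' Execute a protocol and emit a timestamped event log
#'
#' Steps run sequentially and contiguously; sample injection is a
#' zero-duration event and spin ramps are ignored. The heating step
#' delegates to the temperature controller when `plant`/`tocs` are
#' supplied; by default its calibration phase is counted inside the
#' printed step duration (the controller holds for the remainder), or it
#' can be prepended with `calibration = "prepend"`.
#'
#' @param steps a protocol data.frame; must validate cleanly.
#' @param plant,tocs,cfg optional controller hooks ([plant_params()],
#'   [tocs_model()], [controller_config()]); when NULL the heating step is
#'   executed as a plain timed event.
#' @param rng_seed seed for the controller's sensor noise.
#' @param calibration `"included"` (calibration inside the printed heating
#'   duration) or `"prepend"` (added before it).
#' @return a list of class `protocol_run`: `events` data.frame
#'   (`step_index`, `operation`, `start_s`, `end_s`, `rpm`),
#'   `total_duration`, and `control` (controller results or NULL).
#' @export
simulate_protocol <- function(steps, plant = NULL, tocs = NULL,
                              cfg = controller_config(), rng_seed = NULL,
                              calibration = c("included", "prepend")) {
  calibration <- match.arg(calibration)
  stopifnot(is.data.frame(steps))
  report <- validate_protocol(steps)
  if (!report$valid) {
    stop_invalid("invalid protocol: ",
                 paste(report$violations, collapse = "; "))
  }
  n <- nrow(steps)
  events <- data.frame(step_index = integer(0), operation = character(0),
                       start_s = numeric(0), end_s = numeric(0),
                       rpm = numeric(0), stringsAsFactors = FALSE)
  control <- NULL
  t_now <- 0
  for (i in seq_len(n)) {
    st <- steps[i, ]
    dur <- if (is.na(st$duration)) 0 else st$duration
    if (st$operation == "laser_heating" && !is.null(plant) && !is.null(tocs)) {
      res <- tryCatch(
        if (calibration == "included") {
          run_control(plant, tocs, cfg, rng_seed = rng_seed,
                      total_duration = dur)
        } else {
          run_control(plant, tocs, cfg, rng_seed = rng_seed,
                      hold_duration = dur)
        },
        error = function(e) {
          stop(structure(
            class = c("lodlamp_protocol_error", class(e)),
            list(message = sprintf("step %d (%s): %s", st$index,
                                   st$operation, conditionMessage(e)),
                 call = conditionCall(e))))
        })
      if (calibration == "prepend") dur <- dur + res$calibration_time
      res$trace$time_s <- res$trace$time_s + t_now
      control <- res
    }
    events <- rbind(events, data.frame(
      step_index = st$index, operation = st$operation,
      start_s = t_now, end_s = t_now + dur, rpm = st$spin_speed,
      stringsAsFactors = FALSE))
    t_now <- t_now + dur
  }
  structure(list(events = events, total_duration = t_now, control = control),
            class = "protocol_run")
}

#' @export
print.protocol_run <- function(x, ...) {
  cat(sprintf("Protocol run: %d events, total %.1f s\n",
              nrow(x$events), x$total_duration))
  print(x$events)
  invisible(x)
}
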