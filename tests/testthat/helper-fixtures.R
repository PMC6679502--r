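# Shared fixtures: everything is built in code, nothing is read from disk.

default_plant <- function() calibrate_plant(25, 70, 60)
default_tocs <- function() tocs_model()

quiet_cfg <- function(...) controller_config(...)

# a uniform-colour ROI without touching the generator RNG
uniform_roi <- function(rgb, label = "negative") {
  px <- array(0L, dim = c(30, 30, 3))
  for (ch in 1:3) px[, , ch] <- as.integer(rgb[ch])
  structure(list(pixels = px, label = label, seed = 0L,
                 generator_params = color_model()),
            class = "roi_image")
}

# hand-built control trace at a fixed tick for steady_state_mse tests
flat_trace <- function(temps, phase = "hold", tick = 1) {
  n <- length(temps)
  data.frame(time_s = seq_len(n) * tick, phase = phase, duty = 0.5,
             true_temperature_C = temps, measured_intensity = 0.5,
             estimated_temperature_C = temps, branch = "heating",
             stringsAsFactors = FALSE)
}
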