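# Thermochromic sheet (TOCS) optical model.
#
# The TOCS is a microencapsulated leuco-dye film read by a CCD camera; its
# normalized intensity rises with temperature along an S-shaped curve and
# shows hysteresis: the cooling branch is shifted to lower temperatures
# than the heating branch (phase mismatch at equal temperature). Raw camera
# intensity R is normalized by a per-disc reference R_init to absorb
# chamber-to-chamber fabrication variation.

#' TOCS sensor model
#'
#' Logistic intensity-temperature curves, one per branch. Under the default
#' configuration the heating branch passes through 50% of maximum intensity
#' at exactly 60 degC, the LAMP reaction temperature.
#'
#' @param t50_heating temperature at half-maximum intensity on the heating
#'   branch, degC (default 60).
#' @param t50_cooling same for the cooling branch, degC; must be below
#'   `t50_heating` (hysteresis direction).
#' @param slope_width logistic transition width, degC.
#' @param i_min normalized intensity asymptote at low temperature.
#' @param i_max normalized intensity asymptote at saturation.
#' @param r_init raw-intensity normalization reference, camera units.
#' @return an object of class `tocs_model`.
#' @export
tocs_model <- function(t50_heating = 60, t50_cooling = 57, slope_width = 2.5,
                       i_min = 0, i_max = 1, r_init = 180) {
  check_number(t50_heating, "t50_heating")
  check_number(t50_cooling, "t50_cooling", upper = t50_heating,
               strict_upper = TRUE)
  check_number(slope_width, "slope_width", lower = 0, strict_lower = TRUE)
  check_number(i_min, "i_min", lower = 0)
  check_number(i_max, "i_max", lower = i_min, strict_lower = TRUE)
  check_number(r_init, "r_init", lower = 0, strict_lower = TRUE)
  structure(
    list(t50_heating = t50_heating, t50_cooling = t50_cooling,
         slope_width = slope_width, i_min = i_min, i_max = i_max,
         r_init = r_init),
    class = "tocs_model"
  )
}

#' @export
print.tocs_model <- function(x, ...) {
  cat("TOCS sensor model (logistic, hysteretic)\n")
  cat(sprintf("  t50 heating/cooling : %.2f / %.2f degC\n",
              x$t50_heating, x$t50_cooling))
  cat(sprintf("  slope width         : %.2f degC\n", x$slope_width))
  cat(sprintf("  intensity range     : (%.3f, %.3f)\n", x$i_min, x$i_max))
  cat(sprintf("  R_init              : %.1f camera units\n", x$r_init))
  invisible(x)
}

branch_t50 <- function(model, branch) {
  switch(branch,
         heating = model$t50_heating,
         cooling = model$t50_cooling,
         stop_invalid("unknown branch '", branch,
                      "'; must be 'heating' or 'cooling'"))
}

#' Normalized TOCS intensity at a given temperature
#'
#' Monotone logistic map; the two branches differ only by their
#' half-maximum temperature.
#'
#' @param temp temperature, degC (vectorised).
#' @param branch `"heating"` or `"cooling"`.
#' @param model a [tocs_model()].
#' @return normalized intensity in `(i_min, i_max)`.
#' @export
intensity_from_temperature <- function(temp, branch = c("heating", "cooling"),
                                       model = tocs_model()) {
  stopifnot(inherits(model, "tocs_model"))
  if (!is.numeric(temp) || any(!is.finite(temp))) {
    stop_invalid("temp must be finite numeric")
  }
  branch <- match.arg(branch)
  t50 <- branch_t50(model, branch)
  model$i_min + (model$i_max - model$i_min) *
    stats::plogis((temp - t50) / model$slope_width)
}

#' Temperature recovered from a normalized TOCS intensity
#'
#' Exact inverse of [intensity_from_temperature()] on the same branch.
#' Intensities at or beyond the asymptotes cannot be inverted (sensor
#' saturation).
#'
#' @param intensity normalized intensity, strictly inside
#'   `(i_min, i_max)` (vectorised).
#' @inheritParams intensity_from_temperature
#' @return temperature, degC.
#' @export
temperature_from_intensity <- function(intensity,
                                       branch = c("heating", "cooling"),
                                       model = tocs_model()) {
  stopifnot(inherits(model, "tocs_model"))
  branch <- match.arg(branch)
  if (!is.numeric(intensity) || any(!is.finite(intensity))) {
    stop_invalid("intensity must be finite numeric")
  }
  if (any(intensity <= model$i_min) || any(intensity >= model$i_max)) {
    stop_invalid("intensity out of range: must lie strictly in (",
                 model$i_min, ", ", model$i_max, ") to invert (saturation)")
  }
  t50 <- branch_t50(model, branch)
  frac <- (intensity - model$i_min) / (model$i_max - model$i_min)
  t50 + model$slope_width * stats::qlogis(frac)
}

#' Normalize a raw camera intensity by its initial reference
#'
#' `R / R_init`: per-disc normalization absorbing fabrication variation in
#' the amplification chamber. Values above 1 are permitted.
#'
#' @param raw raw camera intensity (vectorised).
#' @param r_init initial reference intensity, camera units (> 0).
#' @return normalized intensity.
#' @export
normalize_reading <- function(raw, r_init) {
  if (!is.numeric(raw) || any(!is.finite(raw))) {
    stop_invalid("raw must be finite numeric")
  }
  check_number(r_init, "r_init", lower = 0, strict_lower = TRUE)
  raw / r_init
}

#' Simulate one noisy camera reading of the TOCS
#'
#' Adds zero-mean Gaussian camera noise to the noiseless branch intensity
#' and clips to `[0, i_max + 5 * noise_sd]`.
#'
#' @inheritParams intensity_from_temperature
#' @param time reading timestamp, s.
#' @param noise_sd camera noise standard deviation, normalized units.
#' @param rng_seed optional seed making the reading reproducible; when NULL
#'   the current RNG stream is used.
#' @return a one-row data.frame of class `sensor_reading` with columns
#'   `time`, `raw_intensity`, `normalized_intensity`, `branch`.
#' @export
observe <- function(temp, branch = c("heating", "cooling"),
                    model = tocs_model(), noise_sd = 0.01,
                    rng_seed = NULL, time = 0) {
  branch <- match.arg(branch)
  check_number(noise_sd, "noise_sd", lower = 0)
  clean <- intensity_from_temperature(temp, branch, model)
  noisy <- with_seed(rng_seed, clean + stats::rnorm(length(clean), 0, noise_sd))
  noisy <- pmin(pmax(noisy, 0), model$i_max + 5 * noise_sd)
  out <- data.frame(time = time, raw_intensity = noisy * model$r_init,
                    normalized_intensity = noisy, branch = branch,
                    stringsAsFactors = FALSE)
  class(out) <- c("sensor_reading", class(out))
  out
}
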