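test_that("pd_step implements the incremental law with quantization and clipping", {
  cfg <- controller_config(kp = 0.5, kd = 0)
  expect_equal(pd_step(0.2, 0.2, 1, cfg, prev_duty = 0.3), 0.4)
  # zero error leaves the duty unchanged
  expect_equal(pd_step(0, 0, 1, controller_config(), prev_duty = 0.37), 0.37)
  # saturation at the limits
  expect_equal(pd_step(10, 0, 1, controller_config(), prev_duty = 0.5), 1)
  expect_equal(pd_step(-10, 0, 1, controller_config(), prev_duty = 0.5), 0)
  # derivative term
  cfg2 <- controller_config(kp = 0, kd = 2, duty_quantum = 0)
  expect_equal(pd_step(0.1, 0.05, 0.5, cfg2, prev_duty = 0.3),
               0.3 + 2 * 0.05 / 0.5)
  # positional form anchors on the bias instead of the previous duty
  cfg3 <- controller_config(kp = 0.5, kd = 0, form = "positional",
                            duty_bias = 0.2)
  expect_equal(pd_step(0.2, 0.2, 1, cfg3, prev_duty = 0.9), 0.3)
})

test_that("compute_target scales the calibrated maximum", {
  expect_equal(compute_target(1.0, controller_config()), 0.5)
  expect_equal(compute_target(0.8, controller_config()), 0.4)
  expect_equal(compute_target(1.0, controller_config(target_fraction = 0.99)),
               0.99)
  expect_error(compute_target(0, controller_config()),
               class = "lodlamp_invalid_input")
})

test_that("noiseless calibration finds the 70 degC plateau intensity", {
  plant <- default_plant(); tocs <- default_tocs()
  cfg <- controller_config(noise_sd = 0)
  cal <- run_calibration_phase(plant, tocs, cfg)
  i70 <- intensity_from_temperature(70, "heating", tocs)
  expect_lt(abs(cal$i_max - i70), cfg$plateau_epsilon)
  expect_lt(cal$calibration_time, cfg$calibration_timeout)

  # steady state does not depend on heat capacity, only the plateau time does
  slow <- plant_params(ambient_temp = plant$ambient_temp,
                       heat_capacity = 2 * plant$heat_capacity,
                       loss_coeff = plant$loss_coeff,
                       absorbed_power = plant$absorbed_power)
  cal2 <- run_calibration_phase(slow, tocs,
                                controller_config(noise_sd = 0,
                                                  calibration_timeout = 1500))
  expect_lt(abs(cal2$i_max - cal$i_max), cfg$plateau_epsilon)
  expect_gt(cal2$calibration_time, cal$calibration_time)
})

test_that("an unreachable plateau criterion times out", {
  plant <- default_plant(); tocs <- default_tocs()
  cfg <- controller_config(noise_sd = 0.05, plateau_epsilon = 0,
                           calibration_timeout = 30)
  expect_error(run_calibration_phase(plant, tocs, cfg, rng_seed = 1),
               class = "lodlamp_calibration_timeout")
})

test_that("the intensity target maps back to the 60 degC setpoint", {
  plant <- default_plant(); tocs <- default_tocs()
  cal <- run_calibration_phase(plant, tocs, controller_config(noise_sd = 0))
  target <- compute_target(cal$i_max, controller_config())
  expect_lt(abs(temperature_from_intensity(target, "heating", tocs) - 60),
            0.1)
})

test_that("noiseless closed loop holds the chamber near 60 degC", {
  plant <- default_plant(); tocs <- default_tocs()
  cfg <- controller_config(noise_sd = 0, hold_duration = 1200)
  res <- run_control(plant, tocs, cfg)
  hold <- res$trace[res$trace$phase == "hold", ]
  sse <- steady_state_mse(res$trace)
  settled <- hold[hold$time_s >= sse$transient_end_s, ]
  expect_lt(abs(mean(settled$true_temperature_C) - 60), 0.3)
  # bounded actuation and the polymerase-safe band
  expect_true(all(hold$duty >= 0 & hold$duty <= 1))
  expect_true(all(hold$true_temperature_C > 55 &
                    hold$true_temperature_C < 75))
  # phases ordered calibration-then-hold
  expect_identical(unique(res$trace$phase), c("calibration", "hold"))
})

test_that("zero gains freeze the duty and drift toward the duty-0.5 steady state", {
  plant <- default_plant(); tocs <- default_tocs()
  cfg <- controller_config(kp = 0, kd = 0, noise_sd = 0,
                           hold_duration = 900)
  res <- run_control(plant, tocs, cfg)
  hold <- res$trace[res$trace$phase == "hold", ]
  expect_true(all(hold$duty == 0.5))
  expect_lt(abs(mean(tail(hold$true_temperature_C, 60)) - 70), 0.5)
})

test_that("the closed loop is reproducible for a fixed seed", {
  plant <- default_plant(); tocs <- default_tocs()
  cfg <- controller_config(hold_duration = 300)
  a <- run_control(plant, tocs, cfg, rng_seed = 17)
  b <- run_control(plant, tocs, cfg, rng_seed = 17)
  expect_identical(a, b)
  c <- run_control(plant, tocs, cfg, rng_seed = 18)
  expect_false(identical(a$trace$measured_intensity,
                         c$trace$measured_intensity))
})

test_that("run_closed_loop requires a completed calibration", {
  expect_error(run_closed_loop(default_plant(), default_tocs(),
                               controller_config()),
               class = "lodlamp_invalid_input")
})

test_that("steady_state_mse agrees with hand-built traces", {
  # constant at the setpoint
  tr <- flat_trace(rep(60, 200))
  expect_equal(steady_state_mse(tr)$mse, 0)
  # settles after 100 s, then alternates 60 +/- 0.4: MSE 0.16
  temps <- c(seq(75, 60.6, length.out = 100), rep(c(60.4, 59.6), 150))
  tr2 <- flat_trace(temps)
  res <- steady_state_mse(tr2)
  expect_equal(res$mse, 0.16)
  expect_equal(res$transient_end_s, 101)
  # transient that never ends
  expect_error(steady_state_mse(flat_trace(rep(75, 300))),
               class = "lodlamp_not_settled")
  expect_error(steady_state_mse(flat_trace(rep(60, 50), phase = "calibration")),
               class = "lodlamp_invalid_input")
})
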