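# Voltage-step analysis: steady-state I-V, leak subtraction, difference
# currents, sodium-transient detection, passive properties.

passive_rec <- generate_voltage_steps("passive", step_protocol(),
                                      rest_mv = -80, r_leak_mohm = 100,
                                      noise_sd_pa = 0)

test_that("steady-state I-V of a passive cell is Ohm's law", {
  curve <- measure_steady_state(passive_rec)
  # slope must be 1000/R = 10 pA/mV, intercept fixed by Vrest = -80
  fit <- lm(curve$currents ~ curve$voltages)
  expect_equal(unname(coef(fit)[2]), 10, tolerance = 1e-9)
  expect_lt(max(abs(resid(fit))), 1e-9)
  expect_equal(curve$currents[curve$voltages == -80], 0, tolerance = 1e-9)
  expect_false(curve$leak_subtracted)
})

test_that("measurement windows are validated and constant traces average exactly", {
  p <- step_protocol(levels = c(-100, -80, -60), onset_ms = 10, offset_ms = 60)
  traces <- matrix(rep(c(-5, 0, 5), each = length(p$time_ms)),
                   ncol = 3)
  rec <- voltage_step_recording(p, traces)
  curve <- measure_steady_state(rec, window = c(40, 60))
  expect_equal(curve$currents, c(-5, 0, 5))
  expect_error(measure_steady_state(rec, window = c(55, 70)), "epoch")
  # single-step protocol gives a single-point curve
  single <- voltage_step_recording(step_protocol(levels = -40),
                                   matrix(2, length(step_protocol(levels = -40)$time_ms), 1))
  expect_equal(length(measure_steady_state(single)$currents), 1L)
})

test_that("leak subtraction zeroes an ohmic curve and recovers a Boltzmann component", {
  v <- seq(-120, 40, by = 10)
  ohmic <- iv_curve(v, 12 * v + 960)
  sub <- leak_subtract(ohmic)
  expect_lt(max(abs(sub$currents)), 1e-9)
  expect_true(sub$leak_subtracted)
  expect_equal(sub$leak_fit$slope_pa_per_mv, 12, tolerance = 1e-9)

  # ohmic + sharp outward Boltzmann activating above -40 mV
  boltz <- 400 / (1 + exp(-(v + 20) / 6))
  mixed <- iv_curve(v, 12 * v + 960 + boltz)
  rec_boltz <- leak_subtract(mixed)
  expect_lt(max(abs(rec_boltz$currents - boltz)), 0.5)

  expect_error(leak_subtract(sub), "already")
  expect_error(leak_subtract(ohmic, leak_range = c(-125, -115)), "2 points")
})

test_that("steady-state + leak subtraction removes exactly an added ohmic component", {
  rec <- generate_voltage_steps("rectifier", step_protocol(), noise_sd_pa = 0)
  base <- leak_subtract(measure_steady_state(rec))
  # add a pure ohmic component (2 nS around -60 mV) to every trace
  g_extra <- 2; v_rev <- -60
  p <- rec$protocol
  in_step <- p$time_ms >= p$onset_ms & p$time_ms < p$offset_ms
  traces2 <- rec$traces
  for (j in seq_along(p$levels)) {
    extra <- ifelse(in_step, g_extra * (p$levels[j] - v_rev),
                    g_extra * (p$holding - v_rev))
    traces2[, j] <- traces2[, j] + extra
  }
  aug <- leak_subtract(measure_steady_state(voltage_step_recording(p, traces2)))
  expect_equal(aug$currents, base$currents, tolerance = 1e-6)
})

test_that("condition subtraction isolates the blocker-sensitive current", {
  v <- seq(-80, 40, by = 10)
  control <- iv_curve(v, 5 * v + ifelse(v > -50, 100, 0))
  treated <- iv_curve(v, 5 * v)
  diff <- subtract_conditions(control, treated)
  expect_equal(diff$currents, ifelse(v > -50, 100, 0))
  # identity and anti-symmetry
  expect_true(all(subtract_conditions(control, control)$currents == 0))
  swapped <- subtract_conditions(treated, control)
  expect_equal(swapped$currents, -diff$currents)
  expect_error(subtract_conditions(control, iv_curve(v + 5, 5 * v)), "grid")
})

test_that("sodium-transient detection fires only above -30 mV on constructed traces", {
  expect_false(detect_transient_inward(passive_rec)$detected)

  na_rec <- generate_voltage_steps("rectifier_with_na", step_protocol(),
                                   noise_sd_pa = 0)
  res <- detect_transient_inward(na_rec)
  expect_true(res$detected)
  expect_true(all(res$peaks$step_mV[res$peaks$detected] > -30))
  # every constructed sodium step is found
  expect_setequal(res$peaks$step_mV[res$peaks$detected],
                  step_protocol()$levels[step_protocol()$levels > -30])

  # outward rectification alone must not trigger
  k_rec <- generate_voltage_steps("rectifier", step_protocol(), noise_sd_pa = 0)
  expect_false(detect_transient_inward(k_rec)$detected)

  # a transient present only at -40 mV is below the step threshold
  p <- step_protocol(levels = c(-120, -40))
  tr <- matrix(0, length(p$time_ms), 2)
  in_win <- p$time_ms >= p$onset_ms & p$time_ms < p$onset_ms + 4
  tr[in_win, 2] <- -300 * exp(-(p$time_ms[in_win] - p$onset_ms) / 1)
  only40 <- voltage_step_recording(p, tr)
  expect_false(detect_transient_inward(only40)$detected)
  # ... but the same deflection above -30 mV is caught
  p2 <- step_protocol(levels = c(-120, -20))
  only20 <- voltage_step_recording(p2, tr)
  expect_true(detect_transient_inward(only20)$detected)
})

test_that("detection is invariant to a constant offset on all traces", {
  na_rec <- generate_voltage_steps("rectifier_with_na", step_protocol(),
                                   noise_sd_pa = 2, seed = 11)
  shifted <- voltage_step_recording(na_rec$protocol, na_rec$traces + 137)
  a <- detect_transient_inward(na_rec)
  b <- detect_transient_inward(shifted)
  expect_equal(b$detected, a$detected)
  expect_equal(b$peaks$peak_deflection_pA, a$peaks$peak_deflection_pA,
               tolerance = 1e-9)
})

test_that("input resistance comes from the local I-V slope", {
  curve <- measure_steady_state(passive_rec)
  est <- estimate_input_resistance(curve, range = c(-90, -70))
  expect_equal(est$r_mohm, 100, tolerance = 1e-6)
  expect_false(est$infinite)
  # zero slope flags infinite resistance instead of crashing
  flat <- iv_curve(c(-90, -80, -70), c(5, 5, 5))
  expect_true(estimate_input_resistance(flat)$infinite)
  # rectifier evaluated below activation equals the leak resistance
  k_rec <- generate_voltage_steps("rectifier", step_protocol(),
                                  r_leak_mohm = 250, noise_sd_pa = 0)
  k_curve <- measure_steady_state(k_rec)
  est_k <- estimate_input_resistance(k_curve, range = c(-120, -90))
  expect_equal(est_k$r_mohm, 250, tolerance = 0.5)
})

test_that("voltage-step recordings round-trip through the long CSV format", {
  rec <- generate_voltage_steps("rectifier_with_na", step_protocol(),
                                noise_sd_pa = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_voltage_steps(rec, path)
  back <- read_voltage_steps(path)
  expect_equal(back$protocol$levels, rec$protocol$levels)
  expect_equal(unname(back$traces), unname(rec$traces), tolerance = 1e-12)
})
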