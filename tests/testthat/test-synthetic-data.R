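test_that("temperature trace follows the step protocol", {
  # zero-lag limit is an exact staircase
  spec <- temperature_protocol(c(11, 13, 15), hold_duration = 10,
                               relax_tau = 0, sample_dt = 0.5)
  tr <- gen_temperature(spec)
  expect_equal(tr$temp_c, rep(c(11, 13, 15), each = 20))
  expect_equal(nrow(tr), 60L)

  # first-order relaxation toward each new target, closed form
  tr <- gen_temperature(temperature_protocol())
  in_second_hold <- tr$time_s >= 240 & tr$time_s < 480
  t_in <- tr$time_s[in_second_hold] - 240
  expect_equal(tr$temp_c[in_second_hold], 13 - 2 * exp(-t_in / 10))
  # stabilized within 0.01 degC of the target by the end of the hold
  expect_lt(abs(tail(tr$temp_c[in_second_hold], 1) - 13), 0.01)

  # degenerate single-target protocol is constant
  tr1 <- gen_temperature(temperature_protocol(11, hold_duration = 60,
                                              sample_dt = 0.1))
  expect_equal(nrow(tr1), 600L)
  expect_true(all(tr1$temp_c == 11))

  # return leg relaxes back to the first target
  trr <- gen_temperature(temperature_protocol(c(11, 13), hold_duration = 60,
                                              return_to_start = TRUE))
  expect_lt(abs(tail(trr$temp_c, 1) - 11), 0.01)

  expect_error(temperature_protocol(hold_duration = -1), "positive")
  expect_error(temperature_protocol(sample_dt = 0), "positive")
  expect_error(temperature_protocol(c(13, 11)), "increasing")
})

test_that("spike-train generator obeys the frequency law", {
  pars <- generator_params(f11 = 1.2, q10 = 1.75, jag_gain = 0,
                           phase_table = phase_table("saline"),
                           phase_jitter_sd = 0)
  # constant 11 degC: all periods exactly 1/f11
  tr <- gen_temperature(temperature_protocol(11, hold_duration = 60))
  ex <- gen_spiketrains(pars, tr)
  expect_equal(ex$cycles$period_s,
               rep(1 / 1.2, nrow(ex$cycles)), tolerance = 1e-9)

  # constant 21 degC: direct evaluation of f11 * q10^(10/10)
  tr21 <- gen_temperature(temperature_protocol(21, hold_duration = 60))
  ex21 <- gen_spiketrains(pars, tr21)
  expect_equal(ex21$cycles$period_s,
               rep(1 / (1.2 * 1.75), nrow(ex21$cycles)), tolerance = 1e-9)
})

test_that("jag transient reaches the linear-ODE steady state on a ramp", {
  # constant ramp lasting >> jag_tau: u -> jag_gain * jag_tau * dT/dt
  rate <- 0.067
  tt <- seq(0, 300, by = 0.1)
  ramp <- data.frame(time_s = tt, temp_c = 11 + rate * tt)
  p0 <- generator_params(f11 = 1.2, q10 = 1.35, jag_gain = 0,
                         phase_table = phase_table("saline"),
                         phase_jitter_sd = 0)
  pj <- generator_params(f11 = 1.2, q10 = 1.35, jag_gain = -0.05,
                         jag_tau = 30, phase_table = phase_table("saline"),
                         phase_jitter_sd = 0)
  f_at <- function(ex, t) {
    k <- which.min(abs(ex$cycles$t_start - t))
    ex$cycles$freq_hz[k]
  }
  dip <- f_at(gen_spiketrains(pj, ramp), 280) -
    f_at(gen_spiketrains(p0, ramp), 280)
  expect_equal(dip, -0.05 * 30 * rate, tolerance = 0.03)
})

test_that("generated spikes are well ordered and reproducible", {
  tr <- gen_temperature(temperature_protocol(c(11, 13), hold_duration = 60))
  pars <- generator_params(phase_jitter_sd = 0.01, seed = 42)
  ex1 <- gen_spiketrains(pars, tr)
  ex2 <- gen_spiketrains(pars, tr)
  expect_identical(ex1, ex2)  # seed determinism, bit for bit

  for (un in c("PD", "LP", "PY")) {
    st <- ex1$spikes$time_s[ex1$spikes$unit == un]
    expect_true(all(diff(st) > 0))
  }

  # jitter-free: every spike lies inside its cycle window
  ex0 <- gen_spiketrains(generator_params(phase_jitter_sd = 0), tr)
  cyc <- ex0$cycles
  last_end <- cyc$t_start[nrow(cyc)] + cyc$period_s[nrow(cyc)]
  expect_true(all(ex0$spikes$time_s >= cyc$t_start[1] - 1e-9))
  expect_true(all(ex0$spikes$time_s <= last_end + 1e-9))
})

test_that("generator rejects infeasible parameters", {
  tr <- gen_temperature(temperature_protocol(c(11, 13), hold_duration = 60))
  # drift so strong the phase table inverts at elevated temperature
  bad <- generator_params(phase_jitter_sd = 0,
                          phase_slopes = c(pd_off = 0, lp_on = 0.2,
                                           lp_off = 0, py_on = 0,
                                           py_off = 0))
  expect_error(gen_spiketrains(bad, tr), "onset < offset.*cycle")
  # transient strong enough to drive f <= 0
  huge <- generator_params(f11 = 0.3, q10 = 1.35, jag_gain = -2,
                           phase_jitter_sd = 0)
  expect_error(gen_spiketrains(huge, tr), "smaller")
  expect_error(generator_params(f11 = -1), "positive")
  expect_error(generator_params(spikes_per_burst = c(PD = 1, LP = 6,
                                                     PY = 6)), ">= 2")
})

test_that("voltage-clamp generator produces the slow exponential", {
  p <- clamp_gen_params(noise_sd = 0, delta_i = 1.5, tau_h = 2,
                        sample_dt = 0.01)
  cl <- gen_clamp_trace(p)
  one <- cl$traces[cl$traces$step_mv == -110, ]
  # I(12) - I(0) = delta_i * (1 - exp(-6))
  expect_equal(tail(one$current_na, 1) - one$current_na[1],
               1.5 * (1 - exp(-12 / 2)), tolerance = 1e-12)
  expect_equal(cl$truth$delta_i_na, rep(1.5, 3))

  # no slow component: trace is flat at i_instant
  flat <- gen_clamp_trace(clamp_gen_params(delta_i = 0, noise_sd = 0,
                                           i_instant = -2))
  expect_true(all(flat$traces$current_na == -2))

  # fixed seed reproduces noisy traces exactly
  pn <- clamp_gen_params(noise_sd = 0.05, seed = 7, sample_dt = 0.01)
  expect_identical(gen_clamp_trace(pn), gen_clamp_trace(pn))
})
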