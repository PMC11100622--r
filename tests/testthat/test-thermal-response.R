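mk_cycles <- function(freq_hz, temp_c) {
  n <- length(freq_hz)
  data.frame(cycle = seq_len(n), t_start = cumsum(c(0, 1 / freq_hz[-n])),
             period_s = 1 / freq_hz, freq_hz = freq_hz, temp_c = temp_c)
}

test_that("holding means apply the 0.3 degC assignment window", {
  cyc <- mk_cycles(rep(1.2, 40), rep(c(10.9, 11.1), 20))
  hm <- suppressWarnings(holding_means(cyc))
  expect_equal(hm$mean_hz[hm$target_c == 11], 1.2)
  expect_equal(hm$n_cycles[hm$target_c == 11], 40L)

  # 11.5 degC is outside |T - 11| <= 0.3: excluded
  cyc2 <- mk_cycles(rep(1.2, 10), rep(11.5, 10))
  expect_warning(hm2 <- holding_means(cyc2, targets = 11), "no cycles")
  expect_true(is.na(hm2$mean_hz))

  cyc3 <- mk_cycles(c(1.0, 1.4), c(11, 11))
  hm3 <- suppressWarnings(holding_means(cyc3))
  expect_equal(hm3$mean_hz[1], 1.2)
  expect_equal(hm3$sd_hz[1], 0.2828, tolerance = 1e-3)
})

test_that("Q10 fit reproduces the endpoint formula and the null case", {
  expect_equal(fit_q10(c(11, 21), c(1.2, 2.1))$q10, 1.75)
  expect_equal(fit_q10(c(11, 21), c(0.9, 1.215))$q10, 1.35)
  # endpoint formula at unequal spacing: (f2/f1)^(10/(T2-T1))
  expect_equal(fit_q10(c(11, 15), c(1, 1.2))$q10, 1.2^(10 / 4))
  # temperature-insensitive limit
  f <- fit_q10(seq(11, 21, 2), rep(1.3, 6))
  expect_equal(f$q10, 1)
  expect_equal(f$f_ref, 1.3)
  expect_error(fit_q10(11, 1.2), "at least two")
  expect_error(fit_q10(c(11, 21), c(-1, 2)), "positive")
})

test_that("frequency difference between holding temperatures", {
  hm <- suppressWarnings(
    holding_means(mk_cycles(c(rep(1.2, 5), rep(2.1, 5)),
                            c(rep(11, 5), rep(21, 5)))))
  expect_equal(delta_f(hm), 0.9)
  expect_equal(delta_f(hm, t_hi = 11, t_lo = 11), 0)
  # negative differences are permitted
  expect_equal(delta_f(hm, t_hi = 11, t_lo = 21), -0.9)
  expect_error(delta_f(hm, t_hi = 15), "no holding mean")
})

test_that("centered moving average truncates symmetrically at edges", {
  expect_equal(smooth_series(rep(2.5, 10), 5), rep(2.5, 10))
  x <- rnorm(20)
  expect_equal(smooth_series(x, 1), x)
  expect_equal(smooth_series(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
  expect_warning(s <- smooth_series(1:4, 10), "global mean")
  expect_equal(s, rep(2.5, 4))
  # output range never exceeds the input range
  set.seed(5)
  for (w in c(3, 10, 30)) {
    y <- rnorm(100)
    sy <- smooth_series(y, w)
    expect_true(all(sy >= min(y) & sy <= max(y)))
  }
})

test_that("jag classifier labels and proportions follow the thresholds", {
  # control-like: frequency rises whenever temperature rises
  n <- 80
  temp <- 11 + cumsum(rep(0.05, n))
  freq <- 1 + 0.03 * (temp - 11)
  jc <- classify_jags(mk_cycles(freq, temp), w_f = 5, w_T = 5)
  expect_equal(jc$p_dec_during_inc, 0)

  # saturated jag: every ramp cycle falls, every stable cycle rises
  temp2 <- c(11 + cumsum(rep(0.05, 40)), rep(13, 40))
  freq2 <- c(2 - cumsum(rep(0.01, 40)), 1.6 + cumsum(rep(0.01, 40)))
  jc2 <- classify_jags(mk_cycles(freq2, temp2), w_f = 1, w_T = 1)
  expect_equal(jc2$p_dec_during_inc, 1)
  expect_equal(jc2$p_inc_during_stable, 1)

  # label partition: each cycle after the first gets exactly one state
  lab <- jc2$cycles[-1, ]
  expect_true(all(lab$temp_state %in% c("increasing", "stable")))
  expect_true(all(lab$freq_state %in%
                    c("increasing", "decreasing", "stable")))

  # empty denominator class reports a missing proportion, not zero
  jc3 <- classify_jags(mk_cycles(rep(1, 40), rep(11, 40)), w_f = 5, w_T = 5)
  expect_true(is.na(jc3$p_dec_during_inc))

  expect_error(classify_jags(mk_cycles(rep(1, 10), rep(11, 10))),
               "at least")
})

test_that("jag proportions rise with transient gain on matched seeds", {
  tr <- gen_temperature(temperature_protocol())
  run <- function(gain, seed) {
    p <- generator_params(jag_gain = gain, seed = seed)
    jc <- classify_jags(extract_phased_cycles(gen_spiketrains(p, tr)$spikes,
                                              tr))
    c(jc$p_dec_during_inc, jc$p_inc_during_stable)
  }
  for (seed in 1:2) {
    res <- vapply(c(0, -0.045, -0.09), run, numeric(2), seed = seed)
    # p_dec_during_inc non-decreasing in |gain|; strict at the extremes
    expect_true(all(diff(res[1, ]) >= 0))
    expect_gt(res[1, 3], res[1, 1])
    expect_gt(res[2, 3], res[2, 1])
  }
})

test_that("phase-constancy fit recovers printed advances and slopes", {
  temps <- seq(11, 21, 2)
  f1 <- fit_phase_slope(temps, seq(0.66, 0.59, length.out = 6), "lp_off")
  expect_equal(f1$slope_per_10C, -0.07)
  expect_equal(f1$direction, "advance")

  f2 <- fit_phase_slope(c(11, 21), c(0.56, 0.42))
  expect_equal(f2$slope_per_10C, -0.14)

  f3 <- fit_phase_slope(temps, rep(0.4, 6))
  expect_equal(f3$slope_per_10C, 0)
  expect_equal(f3$direction, "constant")
  expect_equal(f3$slope_per_10C, 10 * f3$slope)
  expect_error(fit_phase_slope(11, 0.4), "at least two")
})

test_that("generator phase drift is recovered through the pipeline", {
  slopes <- c(pd_off = 0, lp_on = 0, lp_off = -0.007, py_on = 0,
              py_off = 0)
  pars <- generator_params(f11 = 1.2, q10 = 1.75, jag_gain = 0,
                           phase_table = phase_table("saline"),
                           phase_slopes = slopes, phase_jitter_sd = 0)
  tr <- gen_temperature(temperature_protocol(relax_tau = 0,
                                             hold_duration = 120))
  cyc <- extract_phased_cycles(gen_spiketrains(pars, tr)$spikes, tr)
  targets <- seq(11, 21, 2)
  nearest <- targets[vapply(cyc$temp_c,
                            function(x) which.min(abs(targets - x)), 1L)]
  keep <- abs(cyc$temp_c - nearest) <= 0.3
  mean_phase <- tapply(cyc$lp_off[keep], nearest[keep], mean,
                       na.rm = TRUE)
  fit <- fit_phase_slope(as.numeric(names(mean_phase)),
                         as.numeric(mean_phase))
  expect_equal(fit$slope_per_10C, -0.07, tolerance = 0.005)
})

test_that("Q10 survives the generator->pipeline round trip", {
  pars <- generator_params(f11 = 1.2, q10 = 1.75, jag_gain = 0,
                           phase_table = phase_table("saline"),
                           phase_jitter_sd = 0)
  cyc <- rbind(const_hold_cycles(11, pars, hold = 120),
               const_hold_cycles(21, pars, hold = 120))
  q <- fit_q10(holding_means(cyc, targets = c(11, 21)))
  expect_lt(abs(q$q10 - 1.75), 1e-6)

  # with burst-boundary jitter the estimate stays close on the full
  # step protocol (the acceptance suite runs the 100-seed version)
  tr <- gen_temperature(temperature_protocol())
  errs <- vapply(1:5, function(s) {
    pj <- generator_params(f11 = 1.2, q10 = 1.75, jag_gain = 0,
                           phase_table = phase_table("saline"),
                           phase_jitter_sd = 0.01, seed = s)
    cycj <- extract_phased_cycles(gen_spiketrains(pj, tr)$spikes, tr)
    abs(fit_q10(holding_means(cycj))$q10 - 1.75)
  }, numeric(1))
  expect_true(all(errs < 0.05))
})
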