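test_that("burst detection applies the inter-burst-interval rule", {
  b <- detect_bursts(c(0, 0.05, 0.10, 0.50, 0.55))
  expect_equal(b$t_first, c(0, 0.50))
  expect_equal(b$t_last, c(0.10, 0.55))
  expect_equal(b$n_spikes, c(3L, 2L))

  # all gaps >= 200 ms: only singletons, all discarded
  expect_equal(nrow(detect_bursts(c(0, 0.30, 0.60))), 0L)

  # gaps just under the threshold stay within one burst
  b2 <- detect_bursts(c(0, 0.19999, 0.39998))
  expect_equal(b2$n_spikes, 3L)
  # a gap of exactly split_gap starts a new burst (binary-exact times)
  expect_equal(nrow(detect_bursts(c(0, 0.125, 0.375, 0.5),
                                  split_gap = 0.25)), 2L)

  expect_error(detect_bursts(c(0.5, 0.1)), "increasing")
  expect_equal(nrow(detect_bursts(numeric())), 0L)
})

test_that("burst detection matches the brute-force oracle", {
  set.seed(101)
  for (i in 1:100) {
    train <- random_train(200L)
    got <- detect_bursts(train)
    want <- naive_bursts(train)
    expect_equal(got$t_first, want$t_first)
    expect_equal(got$t_last, want$t_last)
    expect_equal(got$n_spikes, want$n_spikes)
  }
})

test_that("cycles run between first PD spikes of consecutive bursts", {
  bursts <- data.frame(unit = "PD", t_first = c(0, 0.8333),
                       t_last = c(0.2, 1.0), n_spikes = 3L)
  cyc <- extract_cycles(bursts)
  expect_equal(nrow(cyc), 1L)
  expect_equal(cyc$period_s, 0.8333)
  expect_equal(cyc$freq_hz, 1 / 0.8333)

  b3 <- data.frame(unit = "PD", t_first = c(0, 1, 2),
                   t_last = c(0.2, 1.2, 2.2), n_spikes = 3L)
  expect_equal(extract_cycles(b3)$freq_hz, c(1, 1))

  b4 <- data.frame(unit = "PD", t_first = c(0, 0.5, 1.5),
                   t_last = c(0.1, 0.6, 1.6), n_spikes = 2L)
  expect_equal(extract_cycles(b4)$freq_hz, c(2, 1))
  # f * P = 1 identity
  cyc4 <- extract_cycles(b4)
  expect_equal(cyc4$freq_hz * cyc4$period_s, rep(1, 2))

  expect_warning(out <- extract_cycles(b4[1, ]), "fewer than two")
  expect_equal(nrow(out), 0L)
})

test_that("phase assignment normalizes latencies by the period", {
  pd <- data.frame(unit = "PD", t_first = c(10, 11), t_last = c(10.19, 11.19),
                   n_spikes = 4L)
  lp <- data.frame(unit = "LP", t_first = 10.40, t_last = 10.66,
                   n_spikes = 5L)
  py <- data.frame(unit = "PY", t_first = 10.58, t_last = 11.05,
                   n_spikes = 5L)
  cyc <- assign_phases(extract_cycles(pd), pd, lp, py)
  expect_equal(cyc$pd_off, 0.19)
  expect_equal(cyc$lp_on, 0.40)
  expect_equal(cyc$lp_off, 0.66)
  expect_equal(cyc$py_on, 0.58)
  # offset past the cycle end is kept raw (> 1) and flagged wrapped
  expect_equal(cyc$py_off, 1.05)
  expect_true(cyc$py_wrapped)
  expect_false(cyc$lp_wrapped)

  # LP burst coincident with the cycle start
  lp0 <- data.frame(unit = "LP", t_first = 10, t_last = 10.3, n_spikes = 4L)
  expect_equal(assign_phases(extract_cycles(pd), pd, lp0)$lp_on, 0)

  # missing LP bursts yield NA, never fabricated zeros
  cyc_na <- assign_phases(extract_cycles(pd), pd, NULL, py)
  expect_true(is.na(cyc_na$lp_on))

  # two LP bursts in one cycle: warning, earlier one used
  lp2 <- data.frame(unit = "LP", t_first = c(10.40, 10.80),
                    t_last = c(10.66, 10.9), n_spikes = 4L)
  expect_warning(cyc2 <- assign_phases(extract_cycles(pd), pd, lp2),
                 "earlier")
  expect_equal(cyc2$lp_on, 0.40)
})

test_that("phase summary reproduces delay, duration and duty cycle", {
  mk <- function(pd_off, lp_on, n = 20, period = 1) {
    data.frame(cycle = 1:n, t_start = (1:n) - 1, period_s = period,
               freq_hz = 1 / period, pd_off = pd_off, lp_on = lp_on,
               lp_off = lp_on + 0.26, py_on = 0.58, py_off = 0.87)
  }
  s1 <- phase_summary(mk(0.19, 0.40))
  expect_equal(s1$delay_pdoff_lpon$mean, 0.21)
  s2 <- phase_summary(mk(0.12, 0.29))
  expect_equal(s2$delay_pdoff_lpon$mean, 0.17)

  # single cycle, P = 1 s, PD off 0.164 -> 164 ms burst duration
  s3 <- phase_summary(mk(0.164, 0.40, n = 1))
  expect_equal(s3$pd_duration_ms$mean, 164)
  expect_equal(s3$duty_cycle[["lp"]], 0.26)

  # permutation invariance over cycle order
  cyc <- mk(0.19, 0.40)
  cyc$pd_off <- cyc$pd_off + seq(0, 0.019, length.out = 20)
  set.seed(3)
  perm <- cyc[sample(nrow(cyc)), ]
  expect_equal(phase_summary(perm)$phases$mean, phase_summary(cyc)$phases$mean)

  # phases with no observations are reported missing, with a warning
  cyc$lp_on <- NA_real_
  expect_warning(s4 <- phase_summary(cyc), "no observations")
  expect_true(is.na(s4$phases$mean[s4$phases$phase == "lp_on"]))
})

test_that("period matching is greedy, tolerance-bounded, one-to-one", {
  mk <- function(periods, lp_on = 0.4) {
    n <- length(periods)
    data.frame(cycle = 1:n, t_start = cumsum(c(0, periods[-n])),
               period_s = periods, freq_hz = 1 / periods, pd_off = 0.19,
               lp_on = lp_on, lp_off = 0.66, py_on = 0.58, py_off = 0.87)
  }
  ref <- mk(c(1, 1.1, 1.2))
  m <- match_periods(ref, ref)
  expect_equal(nrow(m), 3L)
  expect_equal(m$d_lp_on_ms, rep(0, 3))

  m2 <- match_periods(mk(1), mk(c(1.015, 1.3)))
  expect_equal(m2$period_other_s, 1.015)

  expect_warning(m3 <- match_periods(mk(1), mk(1.021)), "no period-matched")
  expect_equal(nrow(m3), 0L)

  # latency difference sign: positive when the other condition is earlier
  m4 <- match_periods(mk(1, lp_on = 0.40), mk(1, lp_on = 0.29))
  expect_equal(m4$d_lp_on_ms[1], (0.40 - 0.29) * 1000)
})

test_that("pipeline recovers generator ground-truth phases when jitter-free", {
  tr <- gen_temperature(temperature_protocol(c(11, 15), hold_duration = 120,
                                             relax_tau = 0))
  pars <- generator_params(f11 = 1.2, q10 = 1.5, jag_gain = 0,
                           phase_table = phase_table("saline"),
                           phase_jitter_sd = 0)
  ex <- gen_spiketrains(pars, tr)
  cyc <- extract_phased_cycles(ex$spikes, tr)
  gt <- ex$cycles[seq_len(nrow(cyc)), ]
  for (ph in c("pd_off", "lp_on", "lp_off", "py_on", "py_off")) {
    expect_equal(cyc[[ph]], gt[[ph]], tolerance = 1e-9)
  }
  expect_equal(cyc$freq_hz * cyc$period_s, rep(1, nrow(cyc)))
  # cycle-local temperature stays within the protocol's range
  expect_true(all(cyc$temp_c >= 11 - 1e-9 & cyc$temp_c <= 15 + 1e-9))
})

test_that("cycles overlapping masked windows are excluded", {
  cyc <- data.frame(cycle = 1:5, t_start = 0:4, period_s = 1,
                    freq_hz = 1)
  kept <- exclude_cycles(cyc, data.frame(start = 1.5, end = 2.5))
  expect_equal(kept$cycle, c(1L, 4L, 5L))
})
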