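# Synthetic-data generators: temperature step protocols, triphasic
# PD/LP/PY spike trains with optional non-monotonic ("jag") frequency
# transients, and voltage-clamp current traces with a slow-activating
# inward current.  These emulate the statistical structure the analysis
# assumes so every downstream stage can be verified against known ground
# truth.

#' Temperature step-protocol specification
#'
#' Describes the bath-temperature protocol used in the experiments the
#' generator emulates: a staircase from 11 to 21 degC in 2 degC steps,
#' each target held for about four minutes while the bath relaxes
#' first-order toward it.
#'
#' @param target_temps Target temperatures in degC, strictly increasing on
#'   the upward leg. Default `c(11, 13, 15, 17, 19, 21)`.
#' @param hold_duration Seconds each target is held (default 240).
#' @param relax_tau First-order bath relaxation time constant in seconds.
#'   `0` gives an idealized zero-lag staircase. Default 10.
#' @param sample_dt Sampling interval of the emitted trace in seconds
#'   (default 0.1).
#' @param return_to_start If `TRUE`, append a final hold returning to the
#'   first target, as at the end of the experimental protocol.
#' @return An object of class `temperature_protocol`.
#' @seealso [gen_temperature()]
#' @export
temperature_protocol <- function(target_temps = c(11, 13, 15, 17, 19, 21),
                                 hold_duration = 240,
                                 relax_tau = 10,
                                 sample_dt = 0.1,
                                 return_to_start = FALSE) {
  if (!is.numeric(target_temps) || length(target_temps) < 1L ||
      anyNA(target_temps)) {
    stop("`target_temps` must be a non-empty numeric vector", call. = FALSE)
  }
  if (length(target_temps) > 1L && any(diff(target_temps) <= 0)) {
    stop("`target_temps` must be strictly increasing on the upward leg",
         call. = FALSE)
  }
  stop_if_not_scalar_pos(hold_duration, "hold_duration")
  stop_if_not_scalar_pos(relax_tau, "relax_tau", allow_zero = TRUE)
  stop_if_not_scalar_pos(sample_dt, "sample_dt")
  structure(
    list(target_temps = as.numeric(target_temps),
         hold_duration = hold_duration,
         relax_tau = relax_tau,
         sample_dt = sample_dt,
         return_to_start = isTRUE(return_to_start)),
    class = "temperature_protocol")
}

#' Generate a temperature trace from a step protocol
#'
#' The trace starts at the first target. At each step change it relaxes
#' exponentially toward the new target with time constant
#' `spec$relax_tau`, and each target is held for `spec$hold_duration`.
#' Samples lie on the half-open grid `t = 0, dt, ..., total - dt`.
#'
#' @param spec A [temperature_protocol()].
#' @return A data frame with columns `time_s` and `temp_c`.
#' @examples
#' tr <- gen_temperature(temperature_protocol())
#' range(tr$temp_c)
#' @export
gen_temperature <- function(spec) {
  if (!inherits(spec, "temperature_protocol")) {
    stop("`spec` must be a temperature_protocol object", call. = FALSE)
  }
  targets <- spec$target_temps
  if (spec$return_to_start && length(targets) > 1L) {
    targets <- c(targets, targets[1L])
  }
  n_seg <- length(targets)
  hold <- spec$hold_duration
  tau <- spec$relax_tau
  dt <- spec$sample_dt

  # value at the start of each segment (exact recursion, no sampling error)
  seg_start_val <- numeric(n_seg)
  seg_start_val[1L] <- targets[1L]
  decay_hold <- if (tau > 0) exp(-hold / tau) else 0
  if (n_seg > 1L) {
    for (j in seq_len(n_seg - 1L)) {
      end_val <- targets[j] + (seg_start_val[j] - targets[j]) * decay_hold
      seg_start_val[j + 1L] <- end_val
    }
  }

  total <- n_seg * hold
  times <- seq(0, total - dt, by = dt)
  seg <- pmin(floor(times / hold) + 1L, n_seg)
  t_in <- times - (seg - 1L) * hold
  decay <- if (tau > 0) exp(-t_in / tau) else 0
  temps <- targets[seg] + (seg_start_val[seg] - targets[seg]) * decay
  data.frame(time_s = times, temp_c = temps)
}

#' Per-condition phase tables
#'
#' Mean onset/offset phases of the three pyloric units at 11 degC, as
#' fractions of the cycle period measured from the first PD spike
#' (PD onset is 0 by construction). The `"saline"` and `"cs"` tables hold
#' the condition means reported for control and cesium-blocked
#' preparations.
#'
#' @param condition `"saline"` or `"cs"`.
#' @return Named numeric vector with entries `pd_off`, `lp_on`, `lp_off`,
#'   `py_on`, `py_off`.
#' @export
phase_table <- function(condition = c("saline", "cs")) {
  condition <- match.arg(condition)
  switch(condition,
    saline = c(pd_off = 0.19, lp_on = 0.40, lp_off = 0.66,
               py_on = 0.58, py_off = 0.87),
    cs = c(pd_off = 0.12, lp_on = 0.29, lp_off = 0.56,
           py_on = 0.60, py_off = 0.90))
}

#' Spike-train generator parameters
#'
#' Parameters of the phenomenological frequency law
#' `f(t) = f11 * q10^((T(t) - 11)/10) + u(t)` with the transient term
#' `du/dt = -u/jag_tau + jag_gain * dT/dt`. Negative `jag_gain` produces
#' the non-monotonic dips ("jags") seen when Ih is blocked: frequency
#' falls while temperature rises, then recovers over roughly `jag_tau`
#' seconds once temperature stabilizes. `jag_gain = 0` disables them.
#' For a 2 degC step filtered by a first-order bath with time constant
#' `tau_b`, the dip depth is
#' `|jag_gain| * 2 * (1/tau_b - 1/jag_tau)^-1 / tau_b *`
#' `((r^(1/(r-1)) - r^(r/(r-1))))` with `r = tau_b/jag_tau`; the default
#' `jag_gain = -0.09` with `jag_tau = 30` s and the default bath
#' (`relax_tau = 10` s) yields dips of about 0.1 Hz with ~30 s recovery.
#'
#' The defaults describe the cesium-blocked condition, where the jag
#' phenomenon expresses (a dip requires
#' `|jag_gain| > f * log(q10)/10 * 1` relative to the steady-state rise);
#' use [condition_params()] for coherent per-condition presets.
#'
#' @param f11 Steady-state pyloric frequency at 11 degC in Hz.
#' @param q10 Temperature coefficient of the frequency (dimensionless).
#' @param jag_gain Transient gain in Hz per degC (`<= 0` for dips; 0
#'   disables).
#' @param jag_tau Relaxation time constant of the transient term, seconds.
#' @param phase_table Named phase fractions at 11 degC, see
#'   [phase_table()].
#' @param phase_slopes Per-phase drift in phase units per degC (named like
#'   `phase_table`; scalar is recycled). Default 0 (phase constancy).
#' @param spikes_per_burst Named integer vector (`PD`, `LP`, `PY`),
#'   spikes placed evenly across each burst. All entries must be >= 2.
#' @param phase_jitter_sd Gaussian jitter applied to each burst's onset
#'   and offset, in phase units (sd is multiplied by the cycle period).
#' @param seed Integer seed for reproducible jitter, or `NULL`.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(f11 = 0.9,
                             q10 = 1.35,
                             jag_gain = -0.09,
                             jag_tau = 30,
                             phase_table = pyloric::phase_table("cs"),
                             phase_slopes = 0,
                             spikes_per_burst = c(PD = 5L, LP = 6L, PY = 6L),
                             phase_jitter_sd = 0.01,
                             seed = NULL) {
  stop_if_not_scalar_pos(f11, "f11")
  stop_if_not_scalar_pos(q10, "q10")
  stop_if_not_scalar_pos(jag_tau, "jag_tau")
  stop_if_not_scalar_pos(phase_jitter_sd, "phase_jitter_sd",
                         allow_zero = TRUE)
  if (!is.numeric(jag_gain) || length(jag_gain) != 1L || !is.finite(jag_gain)) {
    stop("`jag_gain` must be a single finite number", call. = FALSE)
  }
  if (!all(PHASE_NAMES %in% names(phase_table))) {
    stop("`phase_table` must have entries ",
         paste(PHASE_NAMES, collapse = ", "), call. = FALSE)
  }
  phase_table <- phase_table[PHASE_NAMES]
  check_phase_table(phase_table, where = "phase_table")
  if (length(phase_slopes) == 1L) {
    phase_slopes <- setNames(rep(phase_slopes, 5L), PHASE_NAMES)
  }
  if (!all(PHASE_NAMES %in% names(phase_slopes))) {
    stop("`phase_slopes` must be scalar or named like `phase_table`",
         call. = FALSE)
  }
  phase_slopes <- phase_slopes[PHASE_NAMES]
  if (!all(UNIT_NAMES %in% names(spikes_per_burst))) {
    stop("`spikes_per_burst` must have entries PD, LP, PY", call. = FALSE)
  }
  spikes_per_burst <- as.integer(spikes_per_burst[UNIT_NAMES])
  names(spikes_per_burst) <- UNIT_NAMES
  if (any(spikes_per_burst < 2L)) {
    stop("`spikes_per_burst` entries must be >= 2", call. = FALSE)
  }
  structure(
    list(f11 = f11, q10 = q10, jag_gain = jag_gain, jag_tau = jag_tau,
         phase_table = phase_table, phase_slopes = phase_slopes,
         spikes_per_burst = spikes_per_burst,
         phase_jitter_sd = phase_jitter_sd, seed = seed),
    class = "generator_params")
}

# onset < offset within each unit; pd_off > 0
check_phase_table <- function(tab, where = "phase table", cycle = NULL) {
  bad <- !(tab[["pd_off"]] > 0 &&
           tab[["lp_on"]] < tab[["lp_off"]] &&
           tab[["py_on"]] < tab[["py_off"]] &&
           all(tab >= 0))
  if (bad) {
    msg <- if (is.null(cycle)) {
      sprintf("invalid %s: need 0 < pd_off, lp_on < lp_off, py_on < py_off",
              where)
    } else {
      sprintf(
        "phase table violates onset < offset after drift at cycle %d", cycle)
    }
    stop(msg, call. = FALSE)
  }
  invisible(tab)
}

#' Per-condition generator presets
#'
#' Coherent parameter sets for the three experimental conditions:
#' control saline (f11 = 1.2 Hz, Q10 = 1.75, weak transient), cesium
#' (`"cs"`; f11 = 0.9 Hz, Q10 = 1.35, full jag dynamics), and cesium plus
#' picrotoxin (`"cs_ptx"`; pacemaker isolated, control-like temperature
#' sensitivity but pronounced jags). Phase tables and phase-temperature
#' slopes follow the condition means (LP OFF advances ~0.07/10 degC in
#' saline; LP ON ~0.05 and LP OFF ~0.14/10 degC in cesium).
#'
#' @param condition One of `"saline"`, `"cs"`, `"cs_ptx"`.
#' @param ... Overrides passed on to [generator_params()].
#' @return A `generator_params` object.
#' @export
condition_params <- function(condition = c("saline", "cs", "cs_ptx"), ...) {
  condition <- match.arg(condition)
  slopes0 <- setNames(numeric(5L), PHASE_NAMES)
  base <- switch(condition,
    saline = list(f11 = 1.2, q10 = 1.75, jag_gain = -0.01,
                  phase_table = phase_table("saline"),
                  phase_slopes = replace(slopes0, "lp_off", -0.007)),
    cs = list(f11 = 0.9, q10 = 1.35, jag_gain = -0.09,
              phase_table = phase_table("cs"),
              phase_slopes = replace(slopes0, c("lp_on", "lp_off"),
                                     c(-0.005, -0.014))),
    cs_ptx = list(f11 = 0.9, q10 = 1.7, jag_gain = -0.12,
                  phase_table = phase_table("cs"),
                  phase_slopes = slopes0))
  args <- utils::modifyList(base, list(...))
  do.call(generator_params, args)
}

#' Generate triphasic pyloric spike trains over a temperature trace
#'
#' Integrates the instantaneous-frequency law
#' `f(t) = f11 * q10^((T(t)-11)/10) + u(t)` with
#' `du/dt = -u/jag_tau + jag_gain * dT/dt` (explicit Euler at the
#' temperature sample step), places cycle starts where the phase integral
#' of `f` crosses successive integers, and fills each cycle with PD, LP,
#' and PY bursts at the (optionally temperature-drifting) table phases.
#' Gaussian jitter (`phase_jitter_sd * period`) is applied to each
#' burst's onset and offset before spikes are placed evenly across the
#' burst. The unjittered per-cycle ground truth is returned alongside the
#' spikes.
#'
#' @param params A [generator_params()].
#' @param temp A temperature trace data frame (`time_s`, `temp_c`), e.g.
#'   from [gen_temperature()].
#' @return A list of class `pyloric_synth` with elements `spikes`
#'   (data frame `unit`, `time_s`), `cycles` (ground-truth table:
#'   `cycle`, `t_start`, `period_s`, `freq_hz`, `temp_c`, and the five
#'   unjittered phases), `params`, and `temperature`.
#' @examples
#' tr <- gen_temperature(temperature_protocol(c(11, 13), hold_duration = 60))
#' ex <- gen_spiketrains(generator_params(phase_jitter_sd = 0, seed = 1), tr)
#' head(ex$cycles)
#' @export
gen_spiketrains <- function(params, temp) {
  if (!inherits(params, "generator_params")) {
    stop("`params` must be a generator_params object", call. = FALSE)
  }
  if (!is.data.frame(temp) || !all(c("time_s", "temp_c") %in% names(temp))) {
    stop("`temp` must be a data frame with columns time_s, temp_c",
         call. = FALSE)
  }
  tt <- temp$time_s
  TT <- temp$temp_c
  n <- length(tt)
  if (n < 2L) stop("temperature trace too short", call. = FALSE)
  dts <- diff(tt)
  if (any(dts <= 0)) stop("temperature times must be strictly increasing",
                          call. = FALSE)

  # transient term u by explicit Euler on the temperature grid
  u <- numeric(n)
  if (params$jag_gain != 0) {
    dT <- diff(TT)
    a <- 1 - dts / params$jag_tau
    g <- params$jag_gain * dT
    for (i in seq_len(n - 1L)) u[i + 1L] <- u[i] * a[i] + g[i]
  }
  f <- params$f11 * params$q10^((TT - 11) / 10) + u
  if (any(f <= 0)) {
    stop("transient term drives instantaneous frequency <= 0; ",
         "use a smaller |jag_gain|", call. = FALSE)
  }

  # cycle starts where the phase integral crosses successive integers
  phi <- c(0, cumsum(f[-n] * dts))
  n_cross <- floor(phi[n])
  if (n_cross < 2) stop("simulation interval too short for two cycles",
                        call. = FALSE)
  starts <- approx(phi, tt, xout = 0:n_cross, ties = "ordered")$y
  k <- n_cross                       # number of complete cycles
  t_start <- starts[seq_len(k)]
  period <- diff(starts)
  temp_cyc <- approx(tt, TT, xout = t_start, rule = 2, ties = "ordered")$y

  # unjittered phases per cycle (table + drift), validated after drift
  ph <- outer(temp_cyc - 11, params$phase_slopes) +
    matrix(params$phase_table, nrow = k, ncol = 5L, byrow = TRUE)
  colnames(ph) <- PHASE_NAMES
  bad <- which(!(ph[, "pd_off"] > 0 & ph[, "lp_on"] < ph[, "lp_off"] &
                 ph[, "py_on"] < ph[, "py_off"]) | apply(ph < 0, 1, any))
  if (length(bad)) {
    stop(sprintf(
      "phase table violates onset < offset after drift at cycle %d",
      bad[1L]), call. = FALSE)
  }

  cycles <- data.frame(cycle = seq_len(k), t_start = t_start,
                       period_s = period, freq_hz = 1 / period,
                       temp_c = temp_cyc)
  cycles <- cbind(cycles, as.data.frame(ph))

  # burst boundary times: onset/offset in seconds for each unit and cycle
  bounds <- list(
    PD = cbind(on = t_start, off = t_start + ph[, "pd_off"] * period),
    LP = cbind(on = t_start + ph[, "lp_on"] * period,
               off = t_start + ph[, "lp_off"] * period),
    PY = cbind(on = t_start + ph[, "py_on"] * period,
               off = t_start + ph[, "py_off"] * period))

  if (params$phase_jitter_sd > 0) {
    jit <- with_seed(params$seed,
                     matrix(rnorm(k * 6L), nrow = k, ncol = 6L)) *
      (params$phase_jitter_sd * period)
    j <- 0L
    for (un in UNIT_NAMES) {
      bounds[[un]][, "on"] <- bounds[[un]][, "on"] + jit[, j + 1L]
      bounds[[un]][, "off"] <- bounds[[un]][, "off"] + jit[, j + 2L]
      bounds[[un]][, "off"] <- pmax(bounds[[un]][, "off"],
                                    bounds[[un]][, "on"] + 1e-9)
      j <- j + 2L
    }
  }

  spikes <- lapply(UNIT_NAMES, function(un) {
    ns <- params$spikes_per_burst[[un]]
    on <- bounds[[un]][, "on"]
    off <- bounds[[un]][, "off"]
    frac <- seq(0, 1, length.out = ns)
    tim <- rep(on, each = ns) + rep(frac, times = k) * rep(off - on, each = ns)
    if (any(diff(tim) <= 0)) {
      stop("generated spike times are not strictly increasing for unit ",
           un, "; reduce phase_jitter_sd", call. = FALSE)
    }
    data.frame(unit = un, time_s = tim)
  })
  spikes <- do.call(rbind, spikes)

  structure(list(spikes = spikes, cycles = cycles, params = params,
                 temperature = temp),
            class = "pyloric_synth")
}

#' Idealized regular spike trains from a fixed phase table
#'
#' Constructs perfectly periodic PD/LP/PY trains: `n_cycles` identical
#' cycles of length `period` with bursts spanning the given phase
#' fractions and spikes placed evenly across each burst. Useful for
#' worked examples and exact end-to-end checks of the phase pipeline.
#'
#' @param period Cycle period in seconds.
#' @param n_cycles Number of cycles.
#' @param phase_table Named phase fractions, see [phase_table()].
#' @param spikes_per_burst Named integer vector (`PD`, `LP`, `PY`).
#' @return Data frame with columns `unit`, `time_s`.
#' @export
gen_regular_trains <- function(period = 1, n_cycles = 50,
                               phase_table = pyloric::phase_table("saline"),
                               spikes_per_burst = c(PD = 5L, LP = 6L,
                                                    PY = 6L)) {
  stop_if_not_scalar_pos(period, "period")
  check_phase_table(phase_table[PHASE_NAMES])
  starts <- (seq_len(n_cycles) - 1L) * period
  seg <- function(on, off, ns) {
    frac <- seq(0, 1, length.out = ns)
    rep(starts + on * period, each = ns) + rep(frac * (off - on) * period,
                                               times = n_cycles)
  }
  tab <- phase_table
  do.call(rbind, list(
    data.frame(unit = "PD",
               time_s = seg(0, tab[["pd_off"]], spikes_per_burst[["PD"]])),
    data.frame(unit = "LP",
               time_s = seg(tab[["lp_on"]], tab[["lp_off"]],
                            spikes_per_burst[["LP"]])),
    data.frame(unit = "PY",
               time_s = seg(tab[["py_on"]], tab[["py_off"]],
                            spikes_per_burst[["PY"]]))))
}

#' Voltage-clamp generator parameters
#'
#' Describes a family of hyperpolarizing steps from a -50 mV hold (12 s,
#' -10 mV increments from -100 to -120 mV by default). Each step's
#' current is `i_instant + delta_i * (1 - exp(-t/tau_h))` plus Gaussian
#' noise: an instantaneous (leak) level plus a slow-activating inward
#' component whose amplitude `delta_i` is the ground-truth Ih.
#'
#' @param hold_voltage Holding potential, mV (default -50).
#' @param step_voltages Step command potentials, mV.
#' @param step_duration Step length in seconds (default 12).
#' @param sample_dt Sampling interval in seconds (default 0.001).
#' @param i_instant Instantaneous current per step in nA (recycled).
#' @param delta_i Slow-component amplitude per step in nA (recycled);
#'   the ground truth recovered by [measure_ih()].
#' @param tau_h Activation time constant in seconds (default 2).
#' @param noise_sd Gaussian noise sd in nA.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `clamp_gen_params`.
#' @export
clamp_gen_params <- function(hold_voltage = -50,
                             step_voltages = c(-100, -110, -120),
                             step_duration = 12,
                             sample_dt = 0.001,
                             i_instant = -2,
                             delta_i = 1.5,
                             tau_h = 2,
                             noise_sd = 0,
                             seed = NULL) {
  stop_if_not_scalar_pos(step_duration, "step_duration")
  stop_if_not_scalar_pos(sample_dt, "sample_dt")
  stop_if_not_scalar_pos(tau_h, "tau_h")
  stop_if_not_scalar_pos(noise_sd, "noise_sd", allow_zero = TRUE)
  ns <- length(step_voltages)
  structure(
    list(hold_voltage = hold_voltage,
         step_voltages = step_voltages,
         step_duration = step_duration,
         sample_dt = sample_dt,
         i_instant = rep_len(i_instant, ns),
         delta_i = rep_len(delta_i, ns),
         tau_h = tau_h, noise_sd = noise_sd, seed = seed),
    class = "clamp_gen_params")
}

#' Generate voltage-clamp current traces
#'
#' @param params A [clamp_gen_params()].
#' @return A list of class `clamp_synth`: `traces` (data frame `step_mv`,
#'   `time_s`, `current_na`) and `truth` (data frame `step_mv`,
#'   `delta_i_na` — the generated slow-component amplitudes).
#' @examples
#' cl <- gen_clamp_trace(clamp_gen_params(noise_sd = 0))
#' head(cl$truth)
#' @export
gen_clamp_trace <- function(params) {
  if (!inherits(params, "clamp_gen_params")) {
    stop("`params` must be a clamp_gen_params object", call. = FALSE)
  }
  tvec <- seq(0, params$step_duration, by = params$sample_dt)
  act <- 1 - exp(-tvec / params$tau_h)
  traces <- with_seed(params$seed, {
    out <- lapply(seq_along(params$step_voltages), function(j) {
      cur <- params$i_instant[j] + params$delta_i[j] * act
      if (params$noise_sd > 0) {
        cur <- cur + rnorm(length(tvec), sd = params$noise_sd)
      }
      data.frame(step_mv = params$step_voltages[j], time_s = tvec,
                 current_na = cur)
    })
    do.call(rbind, out)
  })
  structure(
    list(traces = traces,
         truth = data.frame(step_mv = params$step_voltages,
                            delta_i_na = params$delta_i)),
    class = "clamp_synth")
}
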