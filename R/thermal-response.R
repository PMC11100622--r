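# Temperature-aligned analyses: holding-temperature frequency means, Q10
# fitting, frequency differences, moving-average smoothing, the jag
# cycle classifier, and phase-constancy slope fits.

#' Mean frequency at each holding temperature
#'
#' A cycle belongs to a target temperature when its cycle-local mean
#' temperature is within `tol` of the target (0.3 degC by default); a
#' cycle within tolerance of two targets is assigned to the nearer.
#' Cycles matching no target — e.g. cycles during the ramps — are
#' excluded.
#'
#' @param cycles Cycle table with `freq_hz` and `temp_c` columns.
#' @param targets Holding-temperature targets in degC.
#' @param tol Assignment tolerance in degC (default 0.3).
#' @return A data frame of class `thermal_summary` with columns
#'   `target_c`, `temp_mean_c` (mean cycle temperature of the assigned
#'   cycles), `mean_hz`, `sd_hz`, `n_cycles`. Targets with no cycles get
#'   `NA` means and a warning.
#' @export
holding_means <- function(cycles, targets = c(11, 13, 15, 17, 19, 21),
                          tol = 0.3) {
  if (!all(c("freq_hz", "temp_c") %in% names(cycles))) {
    stop("`cycles` needs `freq_hz` and `temp_c` columns", call. = FALSE)
  }
  stop_if_not_scalar_pos(tol, "tol")
  nearest <- vapply(cycles$temp_c,
                    function(x) which.min(abs(targets - x)), 1L)
  dist <- abs(cycles$temp_c - targets[nearest])
  assigned <- ifelse(dist <= tol, nearest, NA_integer_)
  out <- data.frame(target_c = targets, temp_mean_c = NA_real_,
                    mean_hz = NA_real_, sd_hz = NA_real_, n_cycles = 0L)
  for (j in seq_along(targets)) {
    sel <- which(assigned == j)
    out$n_cycles[j] <- length(sel)
    if (length(sel)) {
      out$temp_mean_c[j] <- mean(cycles$temp_c[sel])
      out$mean_hz[j] <- mean(cycles$freq_hz[sel])
      out$sd_hz[j] <- if (length(sel) > 1L) sd(cycles$freq_hz[sel])
                      else NA_real_
    }
  }
  if (any(out$n_cycles == 0L)) {
    warning("no cycles within tolerance of target(s): ",
            paste(out$target_c[out$n_cycles == 0L], collapse = ", "))
  }
  class(out) <- c("thermal_summary", class(out))
  out
}

#' Fit the Q10 temperature coefficient of frequency
#'
#' Unweighted least-squares fit of the temperature-coefficient law
#' `log f = log f_ref + (T - t_ref)/10 * log Q10` over holding means.
#' With exactly two points the fit is exact and reduces to the endpoint
#' formula `Q10 = (f2/f1)^(10/(T2 - T1))`.
#'
#' @param temp_c Temperatures in degC, or a `thermal_summary` from
#'   [holding_means()] (whose `temp_mean_c` is used, falling back to
#'   `target_c`).
#' @param freq_hz Mean frequencies in Hz (omit when `temp_c` is a
#'   `thermal_summary`).
#' @param t_ref Reference temperature in degC (default 11), at which
#'   `f_ref` is reported.
#' @return A list of class `q10_fit`: `q10`, `f_ref`, `slope` (on
#'   log f per 10 degC), `intercept`, `r_squared`, `n`.
#' @examples
#' fit_q10(c(11, 21), c(1.2, 2.1))$q10   # 1.75
#' @export
fit_q10 <- function(temp_c, freq_hz = NULL, t_ref = 11) {
  if (inherits(temp_c, "thermal_summary")) {
    s <- temp_c
    temp_c <- ifelse(is.na(s$temp_mean_c), s$target_c, s$temp_mean_c)
    freq_hz <- s$mean_hz
  }
  keep <- !is.na(temp_c) & !is.na(freq_hz)
  temp_c <- temp_c[keep]
  freq_hz <- freq_hz[keep]
  if (length(temp_c) < 2L) {
    stop("need at least two holding means to fit Q10", call. = FALSE)
  }
  if (any(freq_hz <= 0)) stop("frequencies must be positive", call. = FALSE)
  x <- (temp_c - t_ref) / 10
  fit <- lm(log(freq_hz) ~ x)
  sl <- coef(fit)[[2]]
  r2 <- r_squared(log(freq_hz), fit)
  structure(
    list(q10 = exp(sl), f_ref = exp(coef(fit)[[1]]), slope = sl,
         intercept = coef(fit)[[1]], r_squared = r2, n = length(x),
         t_ref = t_ref),
    class = "q10_fit")
}

#' @export
print.q10_fit <- function(x, ...) {
  cat(sprintf("Q10 = %.4g (f at %.3g degC = %.4g Hz, n = %d, R^2 = %.4f)\n",
              x$q10, x$t_ref, x$f_ref, x$n, x$r_squared))
  invisible(x)
}

#' Frequency difference between two holding temperatures
#'
#' @param summary A `thermal_summary` from [holding_means()].
#' @param t_hi,t_lo Target temperatures in degC (defaults 21 and 11).
#' @return `mean f(t_hi) - mean f(t_lo)` in Hz (negative values allowed).
#' @export
delta_f <- function(summary, t_hi = 21, t_lo = 11) {
  get_mean <- function(tg) {
    i <- match(tg, summary$target_c)
    if (is.na(i) || is.na(summary$mean_hz[i])) {
      stop(sprintf("no holding mean at %g degC", tg), call. = FALSE)
    }
    summary$mean_hz[i]
  }
  get_mean(t_hi) - get_mean(t_lo)
}

#' Centered moving average with edge truncation
#'
#' At index `i` the half-width is `min(floor(window/2), i - 1, n - i)`,
#' i.e. the window is truncated symmetrically at the series edges, so
#' output length equals input length, a constant series is unchanged,
#' and the output range never exceeds the input range.
#'
#' @param values Numeric series (one value per pyloric cycle).
#' @param window Nominal window width in cycles (>= 1); `1` is the
#'   identity.
#' @return Smoothed numeric vector of the same length.
#' @examples
#' smooth_series(c(0, 0, 3, 0, 0), 3)
#' @export
smooth_series <- function(values, window) {
  if (!is.numeric(window) || length(window) != 1L || window < 1) {
    stop("`window` must be a single number >= 1", call. = FALSE)
  }
  n <- length(values)
  if (!n) return(values)
  if (window > n) {
    warning("window exceeds series length; returning the global mean")
    return(rep(mean(values), n))
  }
  half <- floor(window / 2)
  i <- seq_len(n)
  k <- pmin(half, i - 1L, n - i)
  cs <- cumsum(c(0, values))
  (cs[i + k + 1L] - cs[i - k]) / (2 * k + 1)
}

#' Classify pyloric cycles into temperature/frequency states ("jags")
#'
#' Smooths per-cycle frequency and temperature with centered moving
#' averages over `w_f` and `w_T` cycles, takes first differences of the
#' smoothed series between consecutive cycles, and labels each cycle:
#' temperature `increasing` iff its smoothed change exceeds `theta_T`
#' (else `stable`), frequency `decreasing`/`increasing` iff its smoothed
#' change is beyond `-theta_f`/`+theta_f` (else `stable`). The two
#' headline proportions are the fraction of temperature-increasing
#' cycles in which frequency decreased, and the fraction of
#' temperature-stable cycles in which frequency increased — the
#' signature of the non-monotonic "jag" response.
#'
#' @param cycles Cycle table with `freq_hz` and `temp_c`.
#' @param w_f,w_T Smoothing windows in cycles (defaults 30 and 10).
#' @param theta_T Temperature change criterion in degC per cycle
#'   (default 0.01).
#' @param theta_f Frequency change criterion in Hz per cycle
#'   (default 0.002).
#' @return A list of class `jag_classification`: `cycles` (per-cycle
#'   smoothed series, deltas, and `temp_state`/`freq_state` labels; the
#'   first cycle has no delta and carries `NA` labels),
#'   `p_dec_during_inc`, `p_inc_during_stable` (each `NA` when its
#'   denominator class is empty), counts, and the thresholds/windows
#'   used.
#' @export
classify_jags <- function(cycles, w_f = 30, w_T = 10,
                          theta_T = 0.01, theta_f = 0.002) {
  n <- nrow(cycles)
  if (n < w_f + 1) {
    stop(sprintf("need at least w_f + 1 = %d cycles, got %d", w_f + 1, n),
         call. = FALSE)
  }
  f_s <- smooth_series(cycles$freq_hz, w_f)
  t_s <- smooth_series(cycles$temp_c, w_T)
  d_f <- c(NA_real_, diff(f_s))
  d_t <- c(NA_real_, diff(t_s))
  temp_state <- ifelse(d_t > theta_T, "increasing", "stable")
  freq_state <- ifelse(d_f < -theta_f, "decreasing",
                       ifelse(d_f > theta_f, "increasing", "stable"))
  lab <- data.frame(cycle = cycles$cycle, temp_smooth = t_s,
                    freq_smooth = f_s, d_temp = d_t, d_freq = d_f,
                    temp_state = temp_state, freq_state = freq_state)
  inc <- which(temp_state == "increasing")
  sta <- which(temp_state == "stable")
  p_dec_inc <- if (length(inc)) {
    mean(freq_state[inc] == "decreasing")
  } else NA_real_
  p_inc_sta <- if (length(sta)) {
    mean(freq_state[sta] == "increasing")
  } else NA_real_
  structure(
    list(cycles = lab,
         p_dec_during_inc = p_dec_inc,
         p_inc_during_stable = p_inc_sta,
         n_increasing = length(inc), n_stable = length(sta),
         w_f = w_f, w_T = w_T, theta_T = theta_T, theta_f = theta_f),
    class = "jag_classification")
}

#' @export
print.jag_classification <- function(x, ...) {
  cat(sprintf(
    "Jag classification (w_f = %g, w_T = %g, theta_T = %g, theta_f = %g)\n",
    x$w_f, x$w_T, x$theta_T, x$theta_f))
  cat(sprintf(" P(freq decreasing | temp increasing) = %.3f (n = %d)\n",
              x$p_dec_during_inc, x$n_increasing))
  cat(sprintf(" P(freq increasing | temp stable)     = %.3f (n = %d)\n",
              x$p_inc_during_stable, x$n_stable))
  invisible(x)
}

#' Fit the phase-versus-temperature line (phase constancy)
#'
#' Ordinary least squares of mean phase on temperature. A slope of zero
#' is phase constancy; a negative slope is a phase advance with warming
#' (the reported `slope_per_10C` is ten times the per-degC slope).
#'
#' @param temp_c Holding temperatures in degC.
#' @param phase Mean phase at each temperature (phase fractions).
#' @param phase_name Optional label carried into the result.
#' @return A list of class `phase_slope_fit`: `phase_name`, `slope`,
#'   `slope_per_10C`, `intercept`, `r_squared`, `n`, and `direction`
#'   (`"advance"` for negative slopes, `"delay"` for positive,
#'   `"constant"` for zero).
#' @examples
#' fit_phase_slope(seq(11, 21, 2), seq(0.66, 0.59, length.out = 6))
#' @export
fit_phase_slope <- function(temp_c, phase, phase_name = "") {
  keep <- !is.na(temp_c) & !is.na(phase)
  temp_c <- temp_c[keep]
  phase <- phase[keep]
  if (length(temp_c) < 2L) {
    stop("need at least two temperatures with non-missing mean phase",
         call. = FALSE)
  }
  fit <- lm(phase ~ temp_c)
  sl <- coef(fit)[[2]]
  r2 <- r_squared(phase, fit)
  structure(
    list(phase_name = phase_name, slope = sl, slope_per_10C = 10 * sl,
         intercept = coef(fit)[[1]], r_squared = r2, n = length(temp_c),
         direction = if (abs(sl) < 1e-12) "constant"
                     else if (sl < 0) "advance" else "delay"),
    class = "phase_slope_fit")
}

#' @export
print.phase_slope_fit <- function(x, ...) {
  nm <- if (nzchar(x$phase_name)) paste0(x$phase_name, ": ") else ""
  cat(sprintf("%s%s of %.4g phase units per 10 degC (n = %d, R^2 = %.3f)\n",
              nm, x$direction, abs(x$slope_per_10C), x$n, x$r_squared))
  invisible(x)
}
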