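# Burst and phase extraction: labeled spike trains -> bursts -> pyloric
# cycles -> per-neuron phases, summaries, and period-matched samples.

#' Detect bursts in a spike train
#'
#' Groups consecutive spikes separated by less than `split_gap` into
#' bursts; an inter-spike gap of at least `split_gap` (200 ms by default)
#' closes the burst. Groups with fewer than `min_spikes` spikes are
#' discarded.
#'
#' @param times Numeric vector of spike times in seconds, strictly
#'   increasing.
#' @param min_spikes Minimum spikes per burst (default 2).
#' @param split_gap Gap in seconds that separates bursts (default 0.2).
#'   A gap of exactly `split_gap` starts a new burst.
#' @param unit Optional unit label recorded in the output.
#' @return Data frame with one row per burst: `unit`, `t_first`,
#'   `t_last`, `n_spikes`; zero rows for an empty train.
#' @examples
#' detect_bursts(c(0, 0.05, 0.10, 0.50, 0.55))
#' @export
detect_bursts <- function(times, min_spikes = 2L, split_gap = 0.2,
                          unit = NA_character_) {
  if (length(times) == 0L) {
    return(data.frame(unit = character(), t_first = numeric(),
                      t_last = numeric(), n_spikes = integer()))
  }
  if (anyNA(times) || !is.numeric(times)) {
    stop("`times` must be numeric without NA", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  stop_if_not_scalar_pos(split_gap, "split_gap")
  grp <- cumsum(c(1, as.integer(diff(times) >= split_gap)))
  first <- tapply(times, grp, min)
  last <- tapply(times, grp, max)
  n <- tapply(times, grp, length)
  keep <- n >= min_spikes
  out <- data.frame(unit = rep(unit, sum(keep)),
                    t_first = as.numeric(first[keep]),
                    t_last = as.numeric(last[keep]),
                    n_spikes = as.integer(n[keep]))
  rownames(out) <- NULL
  out
}

#' Extract pyloric cycles from PD bursts
#'
#' A cycle runs from the first spike of one PD burst to the first spike
#' of the next; the last burst yields no cycle. Frequency is the
#' reciprocal of the period.
#'
#' @param pd_bursts Burst table from [detect_bursts()] for the PD unit.
#' @return Data frame with columns `cycle`, `t_start`, `period_s`,
#'   `freq_hz` (empty, with a warning, if fewer than two bursts).
#' @export
extract_cycles <- function(pd_bursts) {
  if (nrow(pd_bursts) < 2L) {
    warning("fewer than two PD bursts: no cycles extracted")
    return(data.frame(cycle = integer(), t_start = numeric(),
                      period_s = numeric(), freq_hz = numeric()))
  }
  starts <- pd_bursts$t_first
  period <- diff(starts)
  data.frame(cycle = seq_len(length(starts) - 1L),
             t_start = starts[-length(starts)],
             period_s = period, freq_hz = 1 / period)
}

# onset/offset phases of the unique burst whose first spike falls inside
# each cycle window; earlier burst wins on ambiguity (with a warning)
unit_phases <- function(cycles, bursts, unit) {
  k <- nrow(cycles)
  on <- rep(NA_real_, k)
  off <- rep(NA_real_, k)
  wrapped <- rep(FALSE, k)
  if (!is.null(bursts) && nrow(bursts)) {
    idx <- findInterval(bursts$t_first, cycles$t_start)
    ends <- cycles$t_start + cycles$period_s
    inside <- idx >= 1L & idx <= k & bursts$t_first < ends[pmax(idx, 1L)]
    if (anyDuplicated(idx[inside])) {
      warning(sprintf(
        "multiple %s bursts start within one cycle; using the earlier",
        unit))
    }
    first_in <- !duplicated(idx) & inside
    ci <- idx[first_in]
    on[ci] <- (bursts$t_first[first_in] - cycles$t_start[ci]) /
      cycles$period_s[ci]
    off[ci] <- (bursts$t_last[first_in] - cycles$t_start[ci]) /
      cycles$period_s[ci]
    wrapped[ci] <- off[ci] > 1
  }
  list(on = on, off = off, wrapped = wrapped)
}

#' Assign per-neuron phases to pyloric cycles
#'
#' Phase is the latency of a burst boundary from the cycle's first PD
#' spike, normalized by the period. PD onset is 0 by construction. LP and
#' PY use the burst whose first spike falls in the cycle window
#' `[t_start, t_start + period)`; offsets extending past the cycle end
#' are kept as raw phases > 1 and flagged `*_wrapped` (reducing mod 1
#' would corrupt means near 1). Cycles lacking an LP or PY burst carry
#' `NA` for those phases.
#'
#' @param cycles Cycle table from [extract_cycles()].
#' @param pd_bursts,lp_bursts,py_bursts Burst tables from
#'   [detect_bursts()]; `lp_bursts`/`py_bursts` may be `NULL`.
#' @return `cycles` with columns `pd_off`, `lp_on`, `lp_off`, `py_on`,
#'   `py_off`, `lp_wrapped`, `py_wrapped` added.
#' @export
assign_phases <- function(cycles, pd_bursts, lp_bursts = NULL,
                          py_bursts = NULL) {
  if (!nrow(cycles)) return(cycles)
  # the PD burst defining each cycle start
  m <- match(cycles$t_start, pd_bursts$t_first)
  if (anyNA(m)) {
    stop("every cycle start must be the first spike of a PD burst",
         call. = FALSE)
  }
  cycles$pd_off <- (pd_bursts$t_last[m] - cycles$t_start) / cycles$period_s
  lp <- unit_phases(cycles, lp_bursts, "LP")
  py <- unit_phases(cycles, py_bursts, "PY")
  cycles$lp_on <- lp$on
  cycles$lp_off <- lp$off
  cycles$py_on <- py$on
  cycles$py_off <- py$off
  cycles$lp_wrapped <- lp$wrapped
  cycles$py_wrapped <- py$wrapped
  cycles
}

#' Attach cycle-local temperature
#'
#' Cycle temperature is the mean of the (linearly interpolated)
#' temperature trace over the cycle window `[t_start, t_start + period)`,
#' computed exactly for the piecewise-linear trace via its cumulative
#' trapezoidal integral.
#'
#' @param cycles Cycle table.
#' @param temp Temperature trace data frame (`time_s`, `temp_c`).
#' @return `cycles` with a `temp_c` column added.
#' @export
cycle_temperature <- function(cycles, temp) {
  tt <- temp$time_s
  TT <- temp$temp_c
  if (length(tt) < 2L) stop("temperature trace too short", call. = FALSE)
  cum <- c(0, cumsum((TT[-1] + TT[-length(TT)]) / 2 * diff(tt)))
  cum_at <- function(x) {
    x <- pmin(pmax(x, tt[1L]), tt[length(tt)])
    approx(tt, cum, xout = x, ties = "ordered")$y
  }
  a <- cycles$t_start
  b <- cycles$t_start + cycles$period_s
  cycles$temp_c <- (cum_at(b) - cum_at(a)) / (b - a)
  cycles
}

#' Summarize phases across cycles
#'
#' Per-phase mean and SD over cycles (missing values excluded), the
#' PD-offset-to-LP-onset phase delay computed per cycle then averaged,
#' PD burst duration in ms, and LP/PY duty cycles.
#'
#' @param cycles Phase-filled cycle table from [assign_phases()].
#' @return A list of class `phase_summary`: `phases` (data frame
#'   `phase`, `mean`, `sd`, `n`), `delay_pdoff_lpon` (list `mean`, `sd`,
#'   `n`), `pd_duration_ms`, `duty_cycle` (named: `pd`, `lp`, `py`), and
#'   `n_cycles`.
#' @export
phase_summary <- function(cycles) {
  if (!nrow(cycles)) stop("no cycles to summarize", call. = FALSE)
  stat <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(mean = NA_real_, sd = NA_real_, n = 0))
    c(mean = mean(x), sd = if (length(x) > 1L) sd(x) else NA_real_,
      n = length(x))
  }
  tab <- t(vapply(PHASE_NAMES, function(p) stat(cycles[[p]]), numeric(3)))
  phases <- data.frame(phase = PHASE_NAMES, mean = tab[, "mean"],
                       sd = tab[, "sd"], n = as.integer(tab[, "n"]),
                       row.names = NULL)
  if (any(phases$n == 0)) {
    warning("phase(s) with no observations: ",
            paste(phases$phase[phases$n == 0], collapse = ", "))
  }
  delay <- cycles$lp_on - cycles$pd_off
  ds <- stat(delay)
  dur <- stat(cycles$pd_off * cycles$period_s * 1000)
  duty <- c(pd = stat(cycles$pd_off)[["mean"]],
            lp = stat(cycles$lp_off - cycles$lp_on)[["mean"]],
            py = stat(cycles$py_off - cycles$py_on)[["mean"]])
  structure(
    list(phases = phases,
         delay_pdoff_lpon = list(mean = ds[["mean"]], sd = ds[["sd"]],
                                 n = as.integer(ds[["n"]])),
         pd_duration_ms = list(mean = dur[["mean"]], sd = dur[["sd"]]),
         duty_cycle = duty,
         n_cycles = nrow(cycles)),
    class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat("Phase summary over", x$n_cycles, "cycles\n")
  print(x$phases, digits = 3)
  cat(sprintf("PD off -> LP on delay: %.3f +/- %.3f (n = %d)\n",
              x$delay_pdoff_lpon$mean, x$delay_pdoff_lpon$sd,
              x$delay_pdoff_lpon$n))
  cat(sprintf("PD burst duration: %.0f ms\n", x$pd_duration_ms$mean))
  invisible(x)
}

#' Match cycles by period across conditions
#'
#' Greedy one-to-one matching: each reference cycle, in order, pairs with
#' the still-unmatched other-condition cycle of closest period; a pair is
#' accepted iff `|P_other - P_ref| / P_ref <= rel_tol`. Used to compare
#' latencies between conditions at matched period, removing the
#' period-dependence of raw latencies.
#'
#' @param reference_cycles,other_cycles Phase-filled cycle tables.
#' @param rel_tol Relative period tolerance (default 0.02).
#' @return Data frame of accepted pairs: indices and periods of both
#'   members plus latency differences in ms (`d_pd_off_ms`, `d_lp_on_ms`,
#'   `d_py_on_ms`; reference latency minus other latency, so positive
#'   values mean the other condition fires earlier). Zero rows, with a
#'   warning, if nothing matches.
#' @export
match_periods <- function(reference_cycles, other_cycles, rel_tol = 0.02) {
  if (!nrow(reference_cycles) || !nrow(other_cycles)) {
    stop("both cycle sets must be non-empty", call. = FALSE)
  }
  p_ref <- reference_cycles$period_s
  p_oth <- other_cycles$period_s
  avail <- rep(TRUE, length(p_oth))
  ref_idx <- integer()
  oth_idx <- integer()
  for (i in seq_along(p_ref)) {
    cand <- which(avail)
    if (!length(cand)) break
    j <- cand[which.min(abs(p_oth[cand] - p_ref[i]))]
    if (abs(p_oth[j] - p_ref[i]) / p_ref[i] <= rel_tol) {
      avail[j] <- FALSE
      ref_idx <- c(ref_idx, i)
      oth_idx <- c(oth_idx, j)
    }
  }
  if (!length(ref_idx)) {
    warning("no period-matched pairs within tolerance")
    return(data.frame(ref = integer(), other = integer(),
                      period_ref_s = numeric(), period_other_s = numeric(),
                      d_pd_off_ms = numeric(), d_lp_on_ms = numeric(),
                      d_py_on_ms = numeric()))
  }
  lat_diff <- function(col) {
    r <- reference_cycles[[col]][ref_idx] * p_ref[ref_idx]
    o <- other_cycles[[col]][oth_idx] * p_oth[oth_idx]
    (r - o) * 1000
  }
  data.frame(ref = ref_idx, other = oth_idx,
             period_ref_s = p_ref[ref_idx],
             period_other_s = p_oth[oth_idx],
             d_pd_off_ms = lat_diff("pd_off"),
             d_lp_on_ms = lat_diff("lp_on"),
             d_py_on_ms = lat_diff("py_on"))
}

#' Exclude cycles overlapping masked time windows
#'
#' Drops cycles whose window `[t_start, t_start + period)` overlaps any
#' of the supplied exclusion intervals (e.g. solution-exchange or
#' condition boundaries from experiment metadata).
#'
#' @param cycles Cycle table.
#' @param windows Two-column matrix or data frame of `start`, `end`
#'   times in seconds.
#' @return The filtered cycle table.
#' @export
exclude_cycles <- function(cycles, windows) {
  if (is.null(windows) || !NROW(windows)) return(cycles)
  windows <- as.matrix(windows)
  a <- cycles$t_start
  b <- cycles$t_start + cycles$period_s
  drop <- rep(FALSE, nrow(cycles))
  for (i in seq_len(nrow(windows))) {
    drop <- drop | (a < windows[i, 2] & b > windows[i, 1])
  }
  cycles[!drop, , drop = FALSE]
}

#' Run the full spike-train to phased-cycle pipeline
#'
#' Convenience wrapper: burst detection per unit, cycle extraction from
#' PD bursts, phase assignment, and (optionally) cycle-local temperature.
#'
#' @param spikes Data frame with columns `unit` (PD/LP/PY) and `time_s`.
#' @param temp Optional temperature trace (`time_s`, `temp_c`).
#' @param min_spikes,split_gap Burst-detection settings, see
#'   [detect_bursts()].
#' @return Phase-filled cycle table.
#' @export
extract_phased_cycles <- function(spikes, temp = NULL, min_spikes = 2L,
                                  split_gap = 0.2) {
  stopifnot(all(c("unit", "time_s") %in% names(spikes)))
  bursts <- lapply(setNames(UNIT_NAMES, UNIT_NAMES), function(un) {
    detect_bursts(sort(spikes$time_s[spikes$unit == un]),
                  min_spikes = min_spikes, split_gap = split_gap,
                  unit = un)
  })
  cycles <- extract_cycles(bursts$PD)
  cycles <- assign_phases(cycles, bursts$PD, bursts$LP, bursts$PY)
  if (!is.null(temp)) cycles <- cycle_temperature(cycles, temp)
  cycles
}
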