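# Voltage-clamp Ih quantification: the hyperpolarization-activated
# inward current is slow to activate, so its amplitude is taken as the
# difference between the current needed to hold the hyperpolarization
# initially and at steady state.

#' Measure Ih from one hyperpolarizing step
#'
#' `i_initial` is the mean current over `initial_window` and `i_steady`
#' the mean over `steady_window`; the Ih amplitude is
#' `|i_steady - i_initial|`. Defaults: the initial window is the first
#' 5-20 ms of the step (on synthetic traces there is no capacitive
#' transient to skip; widen or delay it for real recordings) and the
#' steady window is the final second of the step.
#'
#' @param step Data frame with `time_s` (from step onset, strictly
#'   increasing) and `current_na`; an optional `step_mv` column is
#'   carried through.
#' @param initial_window Length-2 numeric, seconds (default
#'   `c(0.005, 0.02)`).
#' @param steady_window Length-2 numeric, seconds; `NULL` (default)
#'   means the last 1 s of the trace.
#' @return A list of class `ih_measurement`: `step_mv`, `i_initial`,
#'   `i_steady`, `delta_i` (magnitude), `delta_signed`, and the windows
#'   used.
#' @examples
#' cl <- gen_clamp_trace(clamp_gen_params(noise_sd = 0))
#' tr <- subset(cl$traces, step_mv == -110)
#' measure_ih(tr)$delta_i
#' @export
measure_ih <- function(step, initial_window = c(0.005, 0.02),
                       steady_window = NULL) {
  stopifnot(all(c("time_s", "current_na") %in% names(step)))
  tt <- step$time_s
  if (is.unsorted(tt, strictly = TRUE)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  t_max <- tt[length(tt)]
  if (is.null(steady_window)) steady_window <- c(t_max - 1, t_max)
  win_ok <- function(w) length(w) == 2L && w[1] < w[2] &&
    w[1] >= tt[1] && w[2] <= t_max
  if (!win_ok(initial_window) || !win_ok(steady_window)) {
    stop("measurement windows must lie within the trace extent",
         call. = FALSE)
  }
  if (initial_window[2] > steady_window[1]) {
    stop("initial and steady windows must not overlap", call. = FALSE)
  }
  win_mean <- function(w) {
    sel <- tt >= w[1] & tt <= w[2]
    if (!any(sel)) stop("no samples inside a measurement window",
                        call. = FALSE)
    mean(step$current_na[sel])
  }
  i_init <- win_mean(initial_window)
  i_steady <- win_mean(steady_window)
  structure(
    list(step_mv = if ("step_mv" %in% names(step)) step$step_mv[1]
                   else NA_real_,
         i_initial = i_init, i_steady = i_steady,
         delta_i = abs(i_steady - i_init),
         delta_signed = i_steady - i_init,
         initial_window = initial_window, steady_window = steady_window),
    class = "ih_measurement")
}

#' Measure Ih on every step of a clamp recording
#'
#' @param traces Data frame with `step_mv`, `time_s`, `current_na`
#'   (e.g. `gen_clamp_trace(...)$traces` or [read_clamp_csv()]).
#' @param ... Passed to [measure_ih()].
#' @return Data frame with one row per step: `step_mv`, `i_initial`,
#'   `i_steady`, `delta_i`, `delta_signed`.
#' @export
measure_ih_all <- function(traces, ...) {
  steps <- unique(traces$step_mv)
  rows <- lapply(steps, function(v) {
    m <- measure_ih(traces[traces$step_mv == v, , drop = FALSE], ...)
    data.frame(step_mv = v, i_initial = m$i_initial,
               i_steady = m$i_steady, delta_i = m$delta_i,
               delta_signed = m$delta_signed)
  })
  do.call(rbind, rows)
}

#' Percent block of Ih across paired conditions
#'
#' Per cell, the reduction is `100 * (1 - delta_cs / delta_saline)`;
#' the mean and SD are taken over cells (so values above 100% within a
#' cell, or negative values flagging potentiation, are retained). Cells
#' whose control amplitude does not exceed `noise_floor` are excluded
#' with a warning.
#'
#' @param delta_saline,delta_cs Paired Ih amplitudes (nA) per cell.
#' @param noise_floor Exclusion threshold for the control amplitude
#'   (default 0).
#' @return A list: `mean`, `sd`, `n`, and the `per_cell` percent
#'   reductions.
#' @examples
#' percent_block(c(1.5, 2.0), c(0.23, 0.1))
#' @export
percent_block <- function(delta_saline, delta_cs, noise_floor = 0) {
  if (length(delta_saline) != length(delta_cs)) {
    stop("inputs must be paired per cell", call. = FALSE)
  }
  if (!length(delta_saline)) stop("no pairs supplied", call. = FALSE)
  keep <- delta_saline > noise_floor
  if (!all(keep)) {
    warning(sum(!keep), " cell(s) excluded: control Ih at or below the ",
            "noise floor")
  }
  if (!any(keep)) stop("all cells excluded", call. = FALSE)
  r <- 100 * (1 - delta_cs[keep] / delta_saline[keep])
  if (any(r < 0)) warning("negative reduction (potentiation) in ",
                          sum(r < 0), " cell(s)")
  list(mean = mean(r), sd = if (length(r) > 1L) sd(r) else NA_real_,
       n = length(r), per_cell = r)
}
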