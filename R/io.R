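# Plain-text interchange: spike, temperature, per-cycle and clamp
# tables as CSV; ground truth and summaries as JSON.

#' Read and write pipeline CSV/JSON files
#'
#' Spike tables have columns `unit`, `time_s`; temperature traces
#' `time_s`, `temp_c`; clamp traces `step_mv`, `time_s`, `current_na`;
#' per-cycle tables whatever columns the pipeline produced.
#'
#' @param path File path.
#' @param x Object to write.
#' @return The read data frame (readers) or `path`, invisibly (writers).
#' @name pyloric_io
NULL

check_cols <- function(df, cols, what) {
  if (!all(cols %in% names(df))) {
    stop(sprintf("%s must have columns: %s", what,
                 paste(cols, collapse = ", ")), call. = FALSE)
  }
  df
}

#' @rdname pyloric_io
#' @export
read_spikes_csv <- function(path) {
  check_cols(read.csv(path), c("unit", "time_s"), "spike CSV")
}

#' @rdname pyloric_io
#' @export
write_spikes_csv <- function(x, path) {
  check_cols(x, c("unit", "time_s"), "spike table")
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pyloric_io
#' @export
read_temperature_csv <- function(path) {
  check_cols(read.csv(path), c("time_s", "temp_c"), "temperature CSV")
}

#' @rdname pyloric_io
#' @export
write_temperature_csv <- function(x, path) {
  check_cols(x, c("time_s", "temp_c"), "temperature trace")
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pyloric_io
#' @export
read_clamp_csv <- function(path) {
  check_cols(read.csv(path), c("step_mv", "time_s", "current_na"),
             "clamp CSV")
}

#' @rdname pyloric_io
#' @export
write_clamp_csv <- function(x, path) {
  check_cols(x, c("step_mv", "time_s", "current_na"), "clamp table")
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pyloric_io
#' @export
read_cycles_csv <- function(path) {
  check_cols(read.csv(path), c("t_start", "period_s", "freq_hz"),
             "cycle CSV")
}

#' @rdname pyloric_io
#' @export
write_cycles_csv <- function(x, path) {
  check_cols(x, c("t_start", "period_s", "freq_hz"), "cycle table")
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic experiment to a directory
#'
#' Emits `spikes.csv`, `temperature.csv`, and the ground-truth cycle
#' table as `ground_truth.json` (with the generator parameters).
#'
#' @param experiment A `pyloric_synth` from [gen_spiketrains()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "pyloric_synth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spikes_csv(experiment$spikes, file.path(dir, "spikes.csv"))
  write_temperature_csv(experiment$temperature,
                        file.path(dir, "temperature.csv"))
  gt <- list(params = unclass(experiment$params),
             cycles = experiment$cycles)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = 12, na = "null")
  invisible(dir)
}
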