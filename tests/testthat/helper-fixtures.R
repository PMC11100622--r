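# shared fixtures: brute-force oracles and constructed spike trains

# independent burst oracle: plain linear scan over maximal runs whose
# consecutive gaps are all strictly below `split_gap`
naive_bursts <- function(times, min_spikes = 2L, split_gap = 0.2) {
  out <- list()
  i <- 1L
  n <- length(times)
  while (i <= n) {
    j <- i
    while (j < n && (times[j + 1L] - times[j]) < split_gap) j <- j + 1L
    if (j - i + 1L >= min_spikes) {
      out[[length(out) + 1L]] <- c(times[i], times[j], j - i + 1L)
    }
    i <- j + 1L
  }
  if (!length(out)) {
    return(data.frame(t_first = numeric(), t_last = numeric(),
                      n_spikes = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(t_first = m[, 1], t_last = m[, 2], n_spikes = as.integer(m[, 3]))
}

# random spike train with a mixture of short and long gaps
random_train <- function(n_max = 200L) {
  n <- sample.int(n_max, 1L)
  cumsum(runif(n, 0, 0.4))
}

# end-to-end delay between PD offset and LP onset from idealized trains
pipeline_delay <- function(period, n_cycles, table) {
  spikes <- gen_regular_trains(period = period, n_cycles = n_cycles,
                               phase_table = table)
  cyc <- extract_phased_cycles(spikes)
  phase_summary(cyc)$delay_pdoff_lpon$mean
}

# jitter-free constant-temperature run through the full phase pipeline
const_hold_cycles <- function(temp_c, params, hold = 240) {
  tr <- gen_temperature(temperature_protocol(temp_c, hold_duration = hold))
  ex <- gen_spiketrains(params, tr)
  extract_phased_cycles(ex$spikes, tr)
}
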