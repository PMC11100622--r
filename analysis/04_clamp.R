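# Voltage-clamp Ih quantification: paired saline/cesium amplitudes per
# cell at 11 and 21 degC from synthetic hyperpolarizing steps, and the
# percent block.

source("analysis/00_config.R")

# per-cell ground-truth amplitudes emulate the reported condition means
# (saline ~1.5 nA at 11 degC, ~3.2 nA at 21 degC; cesium removes ~90%)
N_CELLS <- 7L
set.seed(SEED + 99L)
cell_rows <- list()
for (temp in c(11, 21)) {
  base <- if (temp == 11) 1.5 else 3.2
  for (cell in seq_len(N_CELLS)) {
    d_sal <- max(0.2, rnorm(1, base, base / 3))
    d_cs <- max(0, d_sal * rnorm(1, 0.08, 0.08))
    meas <- function(d, seed) {
      cl <- gen_clamp_trace(clamp_gen_params(delta_i = d, noise_sd = 0.05,
                                             seed = seed,
                                             step_voltages = -110))
      measure_ih(cl$traces)$delta_i
    }
    cell_rows[[paste(temp, cell)]] <- data.frame(
      temp_c = temp, cell = cell,
      delta_saline = meas(d_sal, SEED + 2L * cell),
      delta_cs = meas(d_cs, SEED + 2L * cell + 1L))
  }
}
cells <- do.call(rbind, cell_rows)
write.csv(cells, file.path(RESULTS, "ih_cells.csv"), row.names = FALSE)

for (temp in c(11, 21)) {
  cc <- cells[cells$temp_c == temp, ]
  pb <- percent_block(cc$delta_saline, cc$delta_cs)
  cmp <- paired_compare(cc$delta_saline, cc$delta_cs)
  message(sprintf(
    "%d degC, -110 mV: Ih %.2f +/- %.2f nA (saline) vs %.2f +/- %.2f nA (cesium); block %.0f +/- %.0f%% (%s p = %.2g, n = %d)",
    temp, mean(cc$delta_saline), sd(cc$delta_saline),
    mean(cc$delta_cs), sd(cc$delta_cs), pb$mean, pb$sd,
    cmp$test_name, cmp$p_value, cmp$n))
}
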