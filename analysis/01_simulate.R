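# Simulate the study's recordings: for each of six paired preparations,
# triphasic PD/LP/PY spike trains over the step protocol in saline,
# cesium, and cesium + picrotoxin, written as CSV under scratch/sim/.

source("analysis/00_config.R")

temp_trace <- gen_temperature(protocol)

# Animal-to-animal variability: each preparation draws latent frequency
# and temperature-sensitivity factors shared across its conditions (the
# same animal is recorded in every solution), scaled to the reported
# between-animal spreads (Q10 SD ~0.3 saline / ~0.5 cesium; f11 SD
# ~0.2 Hz). The generator itself models one preparation.
set.seed(SEED)
z_f <- rnorm(N_PREPARATIONS)
z_q <- rnorm(N_PREPARATIONS)
q10_sd <- c(saline = 0.3, cs = 0.5, cs_ptx = 0.4)

for (cond in CONDITIONS) {
  base <- condition_params(cond)
  for (prep in seq_len(N_PREPARATIONS)) {
    pars <- condition_params(
      cond,
      f11 = max(0.4, base$f11 + 0.2 * z_f[prep]),
      q10 = max(1.05, base$q10 + q10_sd[[cond]] * z_q[prep]),
      seed = prep_seed(cond, prep))
    ex <- gen_spiketrains(pars, temp_trace)
    write_synthetic_experiment(ex, prep_dir(cond, prep))
  }
  message(sprintf("%-7s: %d preparations simulated (f11 = %.2g Hz, Q10 = %.3g, jag gain = %.3g)",
                  cond, N_PREPARATIONS, base$f11, base$q10,
                  base$jag_gain))
}
message("raw recordings under ", SCRATCH)
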