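# pyloric

Analysis of pyloric-rhythm frequency and phase under temperature steps
and Ih block.

The pyloric rhythm of the crustacean stomatogastric ganglion is a
triphasic motor pattern produced by the PD, LP, and PY neurons. As
temperature rises from 11 to 21 °C the rhythm's frequency increases
with a temperature coefficient
`f(T) = f_ref · Q10^((T − T_ref)/10)` while the neurons' *phases*
(burst onset/offset latencies normalized by the cycle period) stay
nearly constant. Blocking the hyperpolarization-activated inward
current Ih with Cs⁺ lowers the frequency Q10, phase-advances PD offset
and LP, and exposes non-monotonic frequency transients during
temperature ramps ("jags": frequency falls while temperature rises,
then recovers once it stabilizes).

This package is the full analysis chain for such experiments, written
for electrophysiologists analyzing labeled spike trains:

- **Burst/phase extraction** — `detect_bursts()` (two or more spikes
  with inter-spike gaps under 200 ms), `extract_cycles()` (first PD
  spike to first PD spike), `assign_phases()`, `phase_summary()`,
  `match_periods()`.
- **Thermal response** — `holding_means()` (cycles within 0.3 °C of
  each target), `fit_q10()`, `delta_f()`, `classify_jags()`
  (30/10-cycle moving averages, 0.01 °C and 0.002 Hz per-cycle
  criteria), `fit_phase_slope()`.
- **Voltage-clamp Ih** — `measure_ih()` (ΔI between initial and
  steady-state holding current over a 12 s hyperpolarizing step),
  `percent_block()`.
- **Gated inference** — `paired_compare()` (Shapiro–Wilk-routed paired
  t / Wilcoxon signed-rank), `rm_anova_tukey()`, `bonferroni()`,
  `pearson_corr()`, `build_report()`.
- **Synthetic data** — `gen_temperature()`, `gen_spiketrains()`,
  `gen_clamp_trace()`, `condition_params()`: generators that emulate
  the recordings' statistical structure with known ground truth, so
  every stage of the pipeline is testable end to end.

## Worked example

Simulate a Cs⁺-like preparation over the step protocol (11→21 °C in
2 °C steps, 4 min holds), run the pipeline, and summarize:

```r
library(pyloric)

tr     <- gen_temperature(temperature_protocol())
pars   <- condition_params("cs", seed = 1)
ex     <- gen_spiketrains(pars, tr)
cycles <- extract_phased_cycles(ex$spikes, tr)

fit_q10(holding_means(cycles))
#> Q10 = 1.338 (f at 11 degC = 0.8922 Hz, n = 6, R^2 = 0.9972)

classify_jags(cycles)
#> Jag classification (w_f = 30, w_T = 10, theta_T = 0.01, theta_f = 0.002)
#>  P(freq decreasing | temp increasing) = 0.116 (n = 173)
#>  P(freq increasing | temp stable)     = 0.048 (n = 1308)

phase_summary(cycles[abs(cycles$temp_c - 11) <= 0.3, ])
#> Phase summary over 217 cycles
#>    phase  mean     sd   n
#> 1 pd_off 0.119 0.0129 217
#> 2  lp_on 0.290 0.0135 217
#> 3 lp_off 0.559 0.0116 217
#> 4  py_on 0.600 0.0123 217
#> 5 py_off 0.900 0.0140 217
#> PD off -> LP on delay: 0.171 +/- 0.015 (n = 217)
#> PD burst duration: 132 ms
```

The fitted Q10 recovers the generator's 1.35 within the jitter noise;
the recovered phases match the Cs⁺ phase table (PD off 0.12, LP on
0.29, LP off 0.56), and the jag proportions show frequency falling
during ramps and recovering during holds. A larger fraction of
temperature-increasing cycles with decreasing frequency — and of
stable cycles with increasing frequency — than in a saline run is the
signature of the Ih-block phenotype.

## Analysis workflow

The `analysis/` scripts are thin, ordered drivers over the package that
rebuild the whole study on synthetic data (six paired preparations per
condition, with animal-to-animal parameter spread):

```sh
Rscript analysis/01_simulate.R   # raw spike/temperature CSVs -> scratch/
Rscript analysis/02_phases.R     # cycles, phase tables, delays, matching
Rscript analysis/03_thermal.R    # Q10, delta f, jags, phase slopes
Rscript analysis/04_clamp.R      # Ih amplitudes and percent block
Rscript analysis/05_report.R     # statistics + report bundle
```

Summary tables land in `results/` (`phase_table.csv`,
`thermal_summary.csv`, `report.json`, `report.md`, …).

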