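---
title: "Methods: pyloric rhythm analysis under temperature steps and Ih block"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pyloric rhythm analysis under temperature steps and Ih block}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyloric)
```

# The system and the measurements

The pyloric rhythm of the crustacean stomatogastric ganglion is a
triphasic motor pattern: an electrically coupled pacemaker kernel (AB
plus two PD neurons) sets the cycle frequency, and follower neurons (LP,
then PY) burst in a fixed order within each cycle. Near 11 °C the rhythm
runs at roughly 1 Hz; warming the preparation raises the frequency while
the *phases* — burst onset and offset times normalized by the cycle
period — stay nearly constant. The hyperpolarization-activated inward
current Ih shapes both behaviors: blocking it with extracellular Cs⁺
lowers the frequency's temperature sensitivity, phase-advances PD offset
and LP, and exposes non-monotonic frequency transients ("jags") during
temperature ramps — frequency first falls while temperature rises, then
recovers once it stabilizes.

This package implements the full analysis chain for such experiments,
plus a synthetic generator so every stage can be verified against known
ground truth without laboratory recordings:

1. **Burst/phase extraction** — spike trains to bursts, cycles, phases.
2. **Thermal response** — holding-temperature means, Q10 fits, frequency
   differences, the jag classifier, phase-constancy slopes.
3. **Voltage-clamp Ih quantification** — ΔI from hyperpolarizing steps
   and percent block.
4. **Gated inference** — Shapiro–Wilk-routed paired tests,
   repeated-measures ANOVA with Tukey HSD, Bonferroni adjustment.

# Burst and phase definitions

A **burst** is two or more consecutive spikes of one unit whose
inter-spike gaps are all strictly below 200 ms; a gap of at least
200 ms closes the burst (`detect_bursts()`, `split_gap = 0.2` s). The
same rule is applied to PD, LP, and PY; the threshold is exposed because
the follower-neuron convention is a choice, not a measurement. A
**cycle** runs between the first spikes of two consecutive PD bursts;
frequency is the reciprocal of that period. The **phase** of a burst
boundary is its latency from the cycle's first PD spike divided by the
period, so PD onset is 0 by construction.

Numerical conventions worth stating:

- PY offsets often extend past the cycle end. They are kept as raw
  phases > 1 with a `py_wrapped` flag rather than reduced mod 1:
  near-1 offsets reduced to near-0 would corrupt condition means.
- Cycles missing an LP or PY burst carry `NA` phases — never fabricated
  zeros. When two LP bursts start inside one cycle the earlier is used,
  with a warning.
- Cycle-local temperature is the exact mean of the piecewise-linear
  temperature trace over the cycle window (trapezoidal integral), not a
  nearest-sample lookup.
- Period matching across conditions (`match_periods()`) is greedy
  one-to-one nearest-period matching at a 2 % relative tolerance. The
  experimental description implies matched samples but fixes neither a
  tolerance nor an algorithm; greedy nearest is deterministic and
  order-stable, and the tolerance is a parameter.

# The frequency model and Q10 fitting

Steady-state frequency follows the temperature-coefficient law

$$f(T) = f_{\mathrm{ref}} \cdot Q_{10}^{(T - T_{\mathrm{ref}})/10},
\qquad T_{\mathrm{ref}} = 11\ °\mathrm{C}.$$

`holding_means()` averages cycle frequency at each target temperature
over cycles whose cycle-local temperature lies within 0.3 °C of the
target (a cycle within tolerance of two targets goes to the nearer; at
the default 2 °C spacing this cannot occur). `fit_q10()` fits
$\log f$ against $(T - T_{\mathrm{ref}})/10$ by unweighted least
squares over all holding means, so with exactly two points it reduces
to the endpoint formula $Q_{10} = (f_2/f_1)^{10/(T_2-T_1)}$. The fit
regresses on the *measured* mean cycle temperature per target rather
than the nominal target: with a first-order bath the holds sit slightly
below target on average, and using nominal temperatures would bias the
slope at first order.

# The jag classifier

Per-cycle frequency and temperature are smoothed with centered moving
averages over 30 and 10 cycles respectively (`smooth_series()`), then
differenced between consecutive cycles. A cycle's temperature state is
*increasing* when the smoothed change exceeds 0.01 °C/cycle, else
*stable*; its frequency state is *decreasing*/*increasing* beyond
∓0.002 Hz/cycle, else *stable*. The two headline quantities are

- `p_dec_during_inc` — the fraction of temperature-increasing cycles in
  which frequency decreased, and
- `p_inc_during_stable` — the fraction of temperature-stable cycles in
  which frequency increased.

Choices the underlying description leaves open, and how they were
fixed:

- "Change per cycle" is the first difference of the smoothed series.
  This keeps the thresholds unit-consistent (°C/cycle, Hz/cycle).
- Moving averages are centered with symmetric edge truncation (at index
  $i$ the half-width is $\min(\lfloor w/2\rfloor, i-1, n-i)$, so the
  effective window is the odd width $2k+1$). Centering avoids a
  systematic lag between the temperature and frequency label streams;
  truncation keeps output length equal to input length, leaves constant
  series fixed, and keeps the output inside the input range.
- Strict inequalities at both thresholds; frequency changes within
  ±0.002 Hz/cycle are *stable*. Empty denominator classes yield `NA`
  proportions, never 0.

# The synthetic generator

`gen_temperature()` builds the step protocol: targets 11–21 °C in 2 °C
steps, each held 240 s, the bath relaxing first-order toward each new
target with τ = 10 s (the protocol description gives no bath model;
ramps of ~2 °C over tens of seconds motivate this default, and τ is a
parameter — τ = 0 gives an idealized zero-lag staircase).

`gen_spiketrains()` integrates the instantaneous frequency

$$f(t) = f_{11}\, q_{10}^{(T(t)-11)/10} + u(t), \qquad
\dot u = -u/\tau_u + \gamma\, \dot T,$$

by explicit Euler at the temperature sample step (0.1 s; adequate since
$\tau_u \gg dt$). Cycle starts are the integer crossings of
$\int f\,dt$ (linearly interpolated). Within each cycle, bursts are
placed at the phase-table fractions, optionally drifted linearly in
temperature (`phase_slopes`), spikes evenly spaced within bursts
(intra-burst statistics are unspecified in the source experiments, and
uniform placement makes phase-extraction error interpretable), and
Gaussian jitter (sd = `phase_jitter_sd` × period) applied to burst
onsets/offsets — not individual spikes — before spike placement. The
unjittered cycle table is returned as ground truth, and a fixed seed
reproduces output bit for bit.

The transient term $u$ is a deliberately phenomenological stand-in for
the biophysics (a single linear ODE), calibrated to the observed
behavior: dips of roughly 0.1 Hz that recover over ~30 s once
temperature stabilizes. For a 2 °C step through a first-order bath the
dip depth has the closed form

$$u_{\min} = \gamma\,\frac{\Delta T}{\tau_b}\,
\left(\tfrac{1}{\tau_b} - \tfrac{1}{\tau_u}\right)^{-1}
\left(r^{\frac{r}{1-r}} - r^{\frac{1}{1-r}}\right),
\qquad r = \tau_b/\tau_u,$$

which at τ_b = 10 s, τ_u = 30 s gives $u_{\min} \approx 1.155\,\gamma$.
The default gain γ = −0.09 Hz/°C therefore produces ≈ 0.104 Hz dips;
weaker gains produce dips whose 30-cycle-smoothed slope sits at or
below the 0.002 Hz/cycle criterion and are classified as nothing at
all. A dip expresses only when $|\gamma|$ exceeds the steady-state rise
rate $f\,\ln(q_{10})/10$ per °C, which is why the generator's base
defaults are the Cs⁺-like condition (f₁₁ = 0.9 Hz, Q10 = 1.35).
`condition_params()` provides coherent presets: saline
(f₁₁ = 1.2 Hz, Q10 = 1.75, weak γ = −0.01 reproducing the small nonzero
control proportions), `cs` (full jag dynamics, Cs phase table, LP
drifting −0.005/−0.014 phase per °C), and `cs_ptx` (control-like
sensitivity Q10 = 1.7 with the strongest transient, γ = −0.12, matching
the ordering of stable-increase probabilities across conditions).

`gen_clamp_trace()` emulates voltage-clamp steps from −50 mV to
−100…−120 mV for 12 s: current $I(t) = I_{\mathrm{inst}} + \Delta I\,
(1 - e^{-t/\tau_h})$ plus Gaussian noise, sampled at 1 kHz, with the
slow-component amplitude ΔI recorded as ground truth (τ_h default 2 s).

**What the generator does not emulate:** intracellular voltage
waveforms, synaptic dynamics, spike-sorting errors, electrode drift,
solution-exchange artifacts, capacitive transients in clamp traces, or
any conductance-based mechanism behind the jags. Passing tests
demonstrate that the *analysis* recovers known structure; they cannot
validate the biophysical interpretation of real recordings. The
generator also models a single preparation: animal-to-animal
variability is layered on in the analysis scripts (per-preparation
f₁₁/Q10 draws around condition means with a shared within-animal
factor), not inside the generator.

# Ih quantification

Because Ih activates slowly, its amplitude is the difference between
the current needed to hold the hyperpolarization initially and at
steady state. `measure_ih()` takes window means: the initial window
defaults to 5–20 ms after step onset and the steady window to the final
second of the 12 s step. The windows are not fixed by the experimental
description; they were chosen from the closed-form bias of a
window-mean estimator on $1-e^{-t/\tau_h}$, which keeps the estimate
within ~3 % of truth across τ_h ∈ [0.5, 3] s. An early, short initial
window is essential — by 50–250 ms a τ_h ≈ 2 s current is already ~7 %
activated, which would bias ΔI low by that amount. Synthetic traces
carry no capacitive transient, so starting at 5 ms is safe; for real
recordings both windows are parameters. Any window-mean estimator
necessarily under-reports ΔI as τ_h → 0 (the current fully activates
inside the initial window), so accuracy claims are stated over a τ_h
range rather than asymptotically. No leak subtraction is applied.
`percent_block()` averages per-cell reductions
$100\,(1 - \Delta I_{\mathrm{Cs}}/\Delta I_{\mathrm{saline}})$ — the
mean of ratios, not the ratio of means — excluding cells whose control
amplitude is at the noise floor, and flagging (not clipping) negative
reductions.

# Statistical routing

Paired comparisons are gated on the Shapiro–Wilk test of the paired
differences at α = 0.05 (the gate level is a convention; the routing
rule itself — parametric when normal, signed-rank otherwise — follows
standard practice for paired designs, and differences rather than raw
groups are tested). All tests are two-sided. All-zero differences
return a degenerate signed-rank result (statistic 0, p = 1) with a
warning rather than an error. The within-subject one-way comparison is
fit as a randomized complete block (`aov(value ~ condition + subject)`);
with one observation per cell its condition F equals the
repeated-measures F with df $(k-1,(k-1)(n-1))$, Tukey HSD contrasts are
run only after a significant omnibus test, and with two conditions the
design reduces exactly to the paired t-test ($F = t^2$). Phase-slope
families are Bonferroni-adjusted with m = 10 (five phases × two
conditions).

# Verification strategy and problem sizes

The test-suite anchors are of three kinds: worked examples whose values
are fixed by arithmetic (endpoint Q10 values 1.75 and 1.35; pipeline
delays 0.21 and 0.17; phase advances 0.07 and 0.14 per 10 °C),
independent oracles (a brute-force linear-scan burst detector on 1000
random trains; closed-form window means for the Ih estimator), and
statistical properties at sizes chosen to keep the full suite under a
minute of CPU: Q10 round trips on 100 jittered seeds over the six-step
protocol, jag directionality on 20 matched seed pairs, type-I error of
the gated test on 2000 null replicates at n = 21.

One verification choice deserves emphasis. The jitter-free Q10
round-trip identity (error < 10⁻⁶) is tested on constant-temperature
holds at 11 and 21 °C, where the spike→burst→cycle→fit chain is exact
to machine precision. Under the step protocol the identity cannot hold
at 10⁻⁶: cycles straddling a step whose mean temperature still falls
within 0.3 °C of a target contaminate the holding means at the 10⁻⁵
level regardless of bath speed. That is a property of the measurement
definition, not an implementation error, and the step protocol is
covered instead by the jittered-recovery criterion (within 0.05 in
≥ 95 % of seeds).

# Known limitations

- The jag classifier's proportions depend on the smoothing/threshold
  conventions above; alternative readings of "change per cycle" shift
  the absolute percentages (the directionality across conditions is
  robust in our tests, the absolute values less so).
- `extract_cycles()` trusts PD burst detection; a missed PD burst
  merges two cycles rather than flagging one.
- The generator's phase drift is linear in temperature; real phase
  trajectories need not be.
- `measure_ih()` is a window-mean estimator and inherits its drift
  sensitivity: a linear baseline drift adds drift × (window-center
  separation) to ΔI.

# A worked example

```{r example}
tr <- gen_temperature(temperature_protocol())
pars <- condition_params("cs", seed = 1)
ex <- gen_spiketrains(pars, tr)
cycles <- extract_phased_cycles(ex$spikes, tr)

fit_q10(holding_means(cycles))
classify_jags(cycles)
phase_summary(cycles[abs(cycles$temp_c - 11) <= 0.3, ])
```
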