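# coldburst

Deterministic simulation and analysis of burst firing in mammalian
cold thermoreceptors, built around a coupled phase–temperature model.

Cold receptors are phasic free nerve endings whose spike trains encode
temperature: long multi-spike bursts in the cold, single periodic
spikes ("beating") and skipped cycles in the warm, and a transient
burst of unusually many spikes right after a sudden cooling step.
`coldburst` reproduces these regimes with a one-variable phase model

```
dθ/dt = f1(t) + f2(t)·cos θ,   f1 = b − A·cos φ,   f2 = 1 + A·cos φ,
```

where one full 2π rotation of θ is one action potential and a burst is
in progress while `f1 > f2`.  The drift parameters saturate
sigmoidally in an *effective* temperature,
`b = b0 − b1·tanh(C(Teff − T̄))` (and analogously `A`, `Ω`), and a
cooling step drives `Teff` along a Morse-like relaxation
`Teff(t) = D(1 − e^{−a(t−t̄)})² + T0,eff` that undershoots below the
final temperature — which is what produces the transient peak
response.  The temperature path is integrated jointly with the phase
through the half-width state `w² = Teff − T0,eff`,
`dw/dt = a(w)(√D − w)`.

The package provides, as separate composable pieces:

* parameter sets (saturating and classical linear forms) with
  plain-text config round-tripping — `default_tanh_params()`,
  `roper_linear_params()`, `eval_params()`;
* transition bookkeeping and the Morse-like temperature law —
  `make_transition()`, `morse_teff()`, `width_function()`;
* fixed-step RK4 integration (C++ core) of steady and transient runs —
  `simulate_steady()`, `simulate_transition()`;
* spike/burst analytics: spike detection with hysteresis, closed-form
  and scanned `f1 > f2` windows, spikes-per-burst (SB), burst period
  (BP), ISI histograms and clusters — `detect_spikes()`,
  `overlap_windows()`, `segment_bursts()`, `isi_histogram()`;
* the three calibrations: endpoint calibration of the tanh constants,
  the matching-condition bisection for the width parameter `a`, and
  the exponential fit `a(w) = a0·e^{α(w²+T0,eff)}` —
  `calibrate_tanh_endpoints()`, `find_matching_a()`,
  `fit_width_function()`;
* a deterministic scenario runner with TSV outputs and a CLI —
  `run_scenario()`, `scenario_preset()`, `coldburst_cli()`.

## Worked example

Steady-state sweep — parameters, spikes per burst, burst period and
overlap width Δ across the standard temperatures:

```r
library(coldburst)
ps <- default_tanh_params()
do.call(rbind, lapply(seq(15, 40, 5), function(Te) {
  st <- steady_burst_stats(ps, Te)
  data.frame(Teff = Te, mean_SB = st$mean_SB, mean_BP = st$mean_BP,
             delta = attr(st$windows, "delta"))
}))
#>  Teff mean_SB mean_BP  delta
#>    15      11   591.0 154.01
#>    20       6   369.2  91.78
#>    25       3   241.2  55.78
#>    30       2   167.4  34.85
#>    35       1   124.8  22.54
#>    40       1   100.2  15.15
```

Cooling from low temperatures packs more spikes into each burst
(`mean_SB` falls monotonically with `Teff`), the burst period shrinks
as the modulation speeds up, and at 40 °C only single spikes per cycle
remain — the interspike intervals there are as long as the full
modulation period (beating).

Transient 40 → 15 °C: calibrate the relaxation width by the matching
condition, then simulate and segment bursts:

```r
spec <- make_transition(40, 15)
spec
#> <transition_spec> 40 -> 15 degC  (D = 6.25, T0_eff = 8.75)

mr <- find_matching_a(ps, spec)
mr
#> <match_result> a = 0.00193579 ms^-1  residual = -0.755 ms  (46 evals, converged)

traj <- simulate_transition(ps, spec, a = mr$a, simulation_config(dt = 0.01))
segment_bursts(detect_spikes(traj), overlap_windows(traj))
#> <burst_summary> 8 bursts; mean SB = 11.4; mean BP = 650.5 ms
#>        onset    offset spike_count last_spike
#> 1   47.57937   81.2659           2    76.9460
#> 2  459.24455  752.5595          21   736.8118
#> 3 1399.58792 1590.6862          13  1571.4367
#> 4 2077.98384 2242.1169          11  2223.5206
#> ...
```

The matched width parameter lands within a few percent of the
published 0.002 ms⁻¹.  Burst 2 — the onset burst of the transient
response, riding the undershoot of the effective temperature below
15 °C — carries 21 spikes, far more than the later bursts, which relax
towards the steady-state value at 15 °C (11 spikes per burst).

Scenario presets write the same analyses as TSV tables:

```r
run_scenario("steady_sweep", out_dir = "out/steady")        # or from a shell:
# Rscript -e 'coldburst::coldburst_cli()' preset steady_sweep --out out/steady
```

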