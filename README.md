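# cfclock

Simulation and analysis of a **cell-free genetic clock**: a two-gene
negative-feedback oscillator (a sigma-factor activator and the TetR
repressor) operated in a semi-continuous microfluidic ring reactor and
periodically synchronized to an external zeitgeber signal. The package is
aimed at researchers studying entrainment, period doubling and chaos in
forced biochemical oscillators, and at anyone who needs a reproducible
in-silico stand-in for semi-continuous cell-free experiments.

## The model

The free-running circuit is described by four ODEs for the activator and
repressor mRNAs and proteins,

```
dr_a/dt = alpha_a / (1 + (h/K_h)^n_h)  - (delta + 1/tau_m) r_a
da/dt   = k_TL r_a - delta a
dr_h/dt = alpha_h / (1 + (K_a/a)^n_a) - (delta + 1/tau_m) r_h
dh/dt   = k_TL r_h - delta h
```

plus reporter channels driven by the same mRNAs and an exogenous input
species that is only diluted. The reactor replaces a fraction `R` of its
volume every `t_int` = 15 min, which realizes a dilution rate
`delta = -ln(1-R)/t_int` and sets the oscillator's intrinsic period
`T ~ C*pi/delta`. Feeding the input (purified TetR, or an inducer) every
`k`-th cycle imposes a zeitgeber of period `T_in = k*t_int`; the forced
dynamics are governed by the dimensionless ratio
`lambda = T_in/T = k*(-ln(1-R))/pi`. Depending on `lambda` and the Hill
coefficient `n`, the forced clock entrains (1-cycles), period-doubles
(2- and 4-cycles, including cycles that are *degenerate* in the TetR
channel), or — at high nonlinearity — turns chaotic, which the package
classifies through the rotation number `m` computed from equilibrated
signal maxima.

The analysis layer implements autocorrelation-based period estimation,
free-oscillator phase-diagram metrics (equilibrium amplitude, damping
ratio, equilibration time), maximum return maps, instantaneous
refresh-ratio estimation from reference-dye traces, Hill transfer-curve
fitting with 68% confidence intervals, parameter sensitivity analysis, and
1D/2D bifurcation scans. A synthetic-data generator emulates noisy
fluorescence recordings (calibrated intensity encoding, multiplicative and
additive noise, late-run reactor fatigue) so the whole pipeline can be
validated end to end against known ground truth.

## Worked example

```r
library(cfclock)

params <- preset_free_oscillator(alpha = 3, R = 0.25)
params
#> Oscillator parameters (internal units: nM, s)
#>   transcription  alpha_a = 0.003, alpha_h = 0.003 nM/s (3, 3 pM/s)
#>   Hill           K_a = 20 nM (n_a = 3), K_h = 2 nM (n_h = 3)
#>   translation    k_TL_a = 0.02, k_TL_h = 0.02 1/s
#>   mRNA lifetime  tau_m_a = 720, tau_m_h = 720 s (12, 12 min)
#>   dilution       delta = 0.0003196 1/s (period scale pi/delta = 2.73 h)

trace <- run_reactor(params, reactor_protocol(R = 0.25, n_cycles = 192))
acf_period(trace, channel = "rep_a")
#> Period estimate (acf): 2.550 h (+/- 0.13 h from 19 maxima)
phase_metrics(trace, channel = "rep_a")
#> Phase metrics: regime = sustained (15 maxima)
#>   gamma = 1.006, A_inf = 0.064

forced <- classify_forced_point(preset_forced_oscillator(), lambda = 1.20)
forced$rotation
#> Rotation number m = 4 (DM = 3.75e-11 < 0.1), from 36 maxima
head(return_map(forced$maxima$height), 4)
#>         y_i    y_next
#> 1 21.470219  7.464496
#> 2  7.464496 21.418843
#> 3 21.418843 11.826050
#> 4 11.826050 21.470219
```

The free oscillator at `R = 0.25` runs sustained oscillations with a 2.55 h
period, close to the `pi/delta` = 2.73 h timescale set by the dilution rate
(damping ratio `gamma ~ 1`). Forcing the clock at `lambda = 1.20` lands it
on a 4-cycle: four distinct maxima heights recur in a fixed order, the
four points of the maximum return map.

Higher-level bundles (phase diagram, period-vs-dilution fit, sensitivity,
bifurcation diagrams) are run with `run_study()`, e.g.
`run_study("bifurcation_1d", out_dir = "results/bif1d")`; each bundle
writes CSV tables, a figure and a manifest. A thin command-line wrapper is
installed at `inst/exec/cfclock` for shell use
(`Rscript <path-to-pkg>/exec/cfclock simulate-forced --lambda 1.2 ...`).

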