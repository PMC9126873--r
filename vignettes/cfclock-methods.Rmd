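---
title: "Modeling and analysing a forced cell-free genetic clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and analysing a forced cell-free genetic clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfclock)
```

## The oscillator model

The circuit is a two-gene negative feedback loop: a sigma-factor activator
`a` drives transcription of the TetR repressor `h`, and TetR represses
transcription of the activator. Explicit mRNA species (`r_a`, `r_h`)
provide the delay needed for sustained oscillation, giving four core ODEs
with Hill-type regulation:

$$\dot r_a = \alpha_a \frac{1}{1+(h_{\mathrm{eff}}/K_h)^{n_h}} -
   \Big(\delta + \frac{1}{\tau_{m}}\Big) r_a, \qquad
  \dot a = k_{TL}\, r_a - \delta\, a,$$
$$\dot r_h = \alpha_h \frac{1}{1+(K_a/a)^{n_a}} -
   \Big(\delta + \frac{1}{\tau_{m}}\Big) r_h, \qquad
  \dot h = k_{TL}\, r_h - \delta\, h.$$

Two reporter proteins are co-expressed from the same mRNAs (translation and
dilution only) to mimic fluorescence readout, and an exogenous input
species `x_in` and a reference dye are passively diluted. Forcing enters
through the effective repressor concentration: exogenously added TetR pools
with the endogenous protein ($h_{\mathrm{eff}} = h + x_{in}$), while an
inducer is modeled as 1:1 stoichiometric sequestration
($h_{\mathrm{eff}} = \max(h - x_{in}, 0)$) — the simplest saturating
inactivation mechanism; the binding law is an explicit extension point and
only the pooled-TetR mode is exercised by the bundled analyses. Plotted and
analysed TetR is always the *endogenous* `h` channel, matching what a
TetR-fused reporter would show.

Activation at $a = 0$ is defined by its limit (zero): simulations start
from an empty reactor that fills through feeding, which is self-starting
and reproducible, so the rate law must be defined there.

### Parameters and units

Constructor arguments use the units the quantities are usually quoted in
(transcription in pM/s, mRNA lifetimes in minutes); internally everything
is converted once to nM and seconds. Defaults:

| parameter | meaning | free preset | forced preset |
|---|---|---|---|
| `alpha` | transcription rate | 3 pM/s (0.3–3 realistic) | 5 pM/s |
| `K_a`, `K_h` | Hill thresholds | 20 nM, 2 nM | same |
| `n` | Hill coefficient | 3 | 4 (up to 8 in scans) |
| `k_TL` | translation rate | 0.02 1/s | same |
| `tau_m` | mRNA lifetime | 12 min | same |
| `delta` | dilution rate | from `R`, `t_int` | from `lambda` |

The *system* parameters (`K`, `n`, `k_TL`, `tau_m`) shape the gene transfer
curves; the *control* parameters (`alpha`, `delta`) scale them, which is
visible directly in the protein nullclines
$a(h) = (\alpha_a/\delta)\,k_{TL}\tau_m/(1+(h/K_h)^{n_h})$ and its
counterpart $h(a)$. `fixed_point()` intersects the nullclines by 1-D
root-finding on the monotone composed map; the result is meaningful in the
slow-dilution limit $\delta \ll 1/\tau_m$ where the mRNA quasi-steady state
holds.

## The semi-continuous reactor

The experiment replaces a fraction `R` of the reactor volume every
`t_int = 15` min. `run_reactor()` mirrors this literally: the ODEs are
integrated over each interval *without* dilution terms, and the discrete
map $c_{i+1} = c_i (1-R) + c_{in}$ is applied at each transition, with the
zeitgeber payload $c_{in} = A_{in}$ every $k$-th cycle (cycle 0 included:
`i mod k == 0` is applied literally, so the first cycle receives its feed
but no dilution). Samples are taken at the end of each interval, before
the next dilution — one sample per cycle, like the experimental imaging
cadence.

Carrying all dilution in the discrete map (rather than also leaving
$\delta$ in the within-interval ODEs) is deliberate: the map alone already
realizes the effective rate $\delta = -\ln(1-R)/t_{int}$ at the sampling
times, so keeping both would double-count removal. Two consequences are
used as tests: a non-reacting tracer samples exactly $(1-R)^i$ at cycle
$i$, and the interval-end samples converge to the continuous-dilution
trajectory (`continuous_limit_reference()`) as `t_int` shrinks at fixed
$\delta$.

Integration uses deSolve's `lsoda` (stiff-capable) at `rtol = 1e-6`,
`atol = 1e-9` nM; the tests assert the results are stable under tolerance
tightening. Tiny negative excursions from integrator round-off (below
1e-8 nM) are clipped to zero; stiff solvers also probe slightly negative
states between accepted steps, so the internal derivative kernel clamps
the Hill-function arguments at zero while the exported `ode_rhs()` rejects
negative states outright.

## Period estimation

`acf_period()` mean-subtracts the signal, computes the biased normalized
autocorrelation (normalized to its lag-0 value — the biased estimator has
the smoother tail), interpolates with a cubic spline at 20-fold upsampling
and reports the first local maximum at positive lag. The spline can
overshoot within the first raw sampling interval, so candidate maxima
below one sampling step are discarded (a period that short is unresolvable
anyway). A signal with no interior ACF maximum yields a distinguishable
"no-period" result rather than an error. The reported uncertainty is the
systematic term `period / n_maxima`, shrinking inversely with the number
of observed maxima; the proportionality constant 1 is our choice.

`damped_cosine_period()` fits $A e^{-t/\tau}\cos(2\pi t/T + \phi) + c$ to
the ACF, optionally excluding initial lags; on oscillatory traces it
agrees with the ACF estimator within the stated uncertainty, and on pure
decays it either fails to converge or collapses onto a decay-dominated
solution (fitted period exceeding the data span), which is flagged. The
primary ACF method does not exclude the initial transient by default; the
exclusion option belongs to the damped-cosine variant.

For the period-versus-dilution scaling analysis (`run_study
("period_vs_delta")` and the acceptance script) periods are estimated on
the *equilibrated* part of 120 h simulations (first 24 h discarded): the
scaling law concerns the limit-cycle period, and the large startup
transient of an initially empty reactor otherwise inflates the ACF period
at low dilution, where a 48 h recording contains only 2–3 maxima. Across
refresh ratios 0.1–0.4 the model's pointwise ratio $T\delta/\pi$ rises
from about 0.68 to about 1.13 — the inverse-dilution law is phenomenological,
and its least-squares constant depends on the dilution range included.

## Phase-diagram metrics

`phase_metrics()` classifies a free-running trace over a 48 h horizon.
Maxima and minima are detected with a prominence threshold of 2% of the
dynamic range (suppressing noise-born wiggles; exposed as a parameter).
The damping ratio $\gamma = \langle y_i / y_{i+1} \rangle$ and the
equilibrium amplitude (half the final peak-to-trough span, normalized by
the global maximum) are computed from maxima after an initial 12 h
exclusion window: traces start from an empty reactor, and the approach to
the limit cycle would otherwise push $\gamma$ of genuinely sustained
oscillations above 1. Regimes: *sustained* if $\gamma \le 1.05$ with at
least two maxima (the 0.05 tolerance is a package choice, exposed),
*damped* if $\gamma > 1.05$, *overdamped* with fewer than two maxima, in
which case the exponential equilibration constant $\tau_{eq}$ is fitted on
the full horizon (the transient is what it measures). The two-maxima rule
follows the more specific of the two conventions in circulation for when
$\tau_{eq}$ applies. A flat trace is overdamped with undefined
$\tau_{eq}$.

## Rotation numbers and bifurcation scans

Forced trajectories are classified by the rotation number `m`, the number
of forcing periods the orbit needs to close. The pipeline is:

1. **Equilibrate:** discard the first 500 dilution cycles (125 h).
2. **Detect maxima** of the per-cycle-sampled endogenous TetR signal.
   Maxima closer than half the forcing cadence are merged (a forced orbit
   produces at most one maximum per input period; on noisy traces flat
   peaks otherwise split in two).
3. **Fill degenerate maxima:** where consecutive maxima are more than 20
   cycles apart, insert maxima at the forcing cadence within the gap.
   Orbits can be degenerate in one channel — a period-doubled cycle whose
   second maximum flattens into a shoulder — yet the hidden visit still
   counts towards `m`. Inserted heights are read from the trace at the
   inserted positions (default): for a degenerate 2-cycle the flanking
   real maxima are nearly equal, so interpolating heights *between* them
   would erase the very alternation that makes the orbit a 2-cycle (a
   linear-height variant is kept as an option).
4. **Closure test:** normalize heights by their maximum and compute the
   defect $\Delta M(k)$ between the sequence and itself shifted by $k$;
   `m` is the smallest $k$ with $\Delta M(k) < 0.1$, and trajectories with
   no closure for $k \le 32$ are classified chaotic. The smallest-k rule
   prevents multiples of the true period from being reported.

The default defect aggregation is the maximum absolute pairwise difference
— the strictest test, right for noiseless simulations. For maxima from
noisy recordings use `aggregate = "mean"`: the maximum of ~n independent
noise draws grows with n, so the max-norm defect of a periodic but noisy
sequence exceeds any fixed threshold with near-certainty, while the mean
defect stays near the per-pair noise level (well below 0.1 at 5%
multiplicative noise) for the true period and near the cluster separation
otherwise.

`bifurcation_1d()` scans `lambda` at fixed forcing cadence (`T_in` = 4 h,
`k = 16`): the forcing period is quantized in units of `t_int`, so the
intrinsic period is varied instead through `R`, which is continuous. Each
point runs 500 equilibration plus 576 analysis cycles — 36 forcing
periods, so even a TetR-degenerate 2-cycle leaves more than 32 maxima
after gap filling. `bifurcation_2d()` adds the Hill coefficient as second
axis through the uniform-parameter constructor and records `m` per cell
(1088 analysis cycles, ≥ 64 maxima for a reliable chaos call); failed
cells are flagged and the scan continues. The default `lambda` range for
exploratory scans is 0.5–2.0, covering the entrained, doubled and chaotic
regimes.

Near the chaotic bands the attractor structure is fractal in `lambda`, and
the exact boundaries of periodic windows depend on integrator details;
classifications at single points adjacent to a band boundary should be
read with that in mind (the surrounding band structure is the robust
object). Within the chaotic bands at high `n`, periodic windows (period 3,
5, ...) interrupt the chaos, as expected for the period-doubling route.

`sensitivity_analysis()` re-simulates the free oscillator with each of the
11 model parameters multiplied by 1.3 in turn (a `direction` flag gives
the −30% variant) and re-estimates the period; the dilution-rate
perturbation is realized through the refresh ratio, the control actually
available on the reactor.

## Synthetic data

`generate_experiment()` emulates a microfluidic fluorescence recording:
the mechanistic simulation is converted to raw intensities by the exact
inverse of the calibrated normalization
$c = \frac{I-B}{I_0-B_0}\cdot\frac{I_{0,ref}-B_{0,ref}}{I_{ref}-B_{ref}}
\cdot 1\,\mu M$, then seeded noise is applied: a multiplicative lognormal
factor with unit mean (default CV 5%) on the background-subtracted signal,
then additive Gaussian noise. The multiplicative term acts on the signal
rather than the total intensity because background ROIs are subtracted
frame by frame, cancelling common-mode illumination gain. Noise magnitudes
are calibration knobs of the generator, not measured properties; they are
chosen so that the analysis pipeline behaves like the described
experiments (e.g. Hill-fit confidence intervals at the reported widths).

Reactor fatigue — the ~1 percentage-point decline of the realized refresh
ratio after ~36 h of operation — is emulated as a step drop in the
per-cycle `R` (minimal model consistent with the described behavior; a
linear-ramp alternative is provided). Fatigue lives entirely in the
synthetic-data layer: the mechanistic simulator stays deterministic and
ideal. `generate_reference_trace()` produces the spiked, geometrically
decaying reference-dye channel in closed form, and
`instantaneous_refresh()` recovers $R_t = 1 - I_{t+1}/I_t$ from it, masked
to points with $I_t > 0.3\,I_{max}$; pairs spanning a feed spike are
reported but flagged and excluded from windowed means.

What the generator does *not* emulate: image-level artifacts (pixels,
ROIs, bleaching), reagent-activity decay (a drift in `alpha`), and
correlated noise. Passing the recovery tests therefore shows the analysis
chain is correct and noise-robust at the modeled noise structure, not that
it is robust to every failure mode of real recordings.

## Problem sizes and determinism

The bundled analyses are sized to resolve the qualitative structure in
minutes on one core: free-oscillator runs of 192–480 cycles (48–120 h of
model time), forced classifications of 1076 cycles (500 equilibration +
576 analysis), a 1600-analysis-cycle run for chaos classification, and
coarse default grids for the scans; denser grids are a parameter away.
All simulation is deterministic given tolerances; only the synthetic-data
generator consumes seeds, and identical seeds give byte-identical
datasets.

## Known limitations

- The model omits resource competition (e.g. sigma-factor competition for
  RNA polymerase core), reagent aging, and stochastic copy-number effects;
  it is a deterministic, well-mixed description.
- The inducer mode's 1:1 sequestration is an assumption, not a measured
  binding law.
- Linear stability theory of the free oscillator (Hopf boundaries) is out
  of scope; the phase diagram is classified empirically from simulated
  traces.
- The inverse-dilution period law is phenomenological; its fitted constant
  depends on the dilution range (see the period-estimation section).
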