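---
title: "Temperature-robust action-potential timing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-robust action-potential timing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thermaxon)
```

This vignette is the package's account of its science: the biophysical
model, the numerical scheme, the interpretive decisions taken where the
source material underdetermines the implementation, and what the test suite
does and does not establish.

## The cable model

The axon is a uniform unmyelinated cylinder of diameter $d$ obeying the
cable equation

$$C_m \frac{\partial V}{\partial t} \;=\;
  \frac{d}{4 R_a} \frac{\partial^2 V}{\partial x^2}
  \;-\; \bar g_{Na} m^3 h\,(V - E_{Na})
  \;-\; \bar g_{K} n^4\,(V - E_K)
  \;-\; \bar g_{leak}\,(V - E_{leak}),$$

with $C_m = 1\ \mu F/cm^2$, $R_a = 28\ \Omega\,cm$, $\bar g_{Na} = 0.48$,
$\bar g_K = 1.088$ and $\bar g_{leak} = 0.0016\ S/cm^2$, and a resting
potential of $-60$ mV.  Each gating variable $x \in \{m, h, n\}$ relaxes
toward a logistic steady state

$$x_\infty(V) = \frac{1}{1 + e^{-k\,(V_{1/2} - V)}}$$

with the constants (per mV / mV):
$m$: $k=-0.4$, $V_{1/2}=-36$; $h$: $k=1$, $V_{1/2}=-39.5$;
$n$: $k=-0.125$, $V_{1/2}=-33$.

**Time-constant curves.**  The gate time constants are saturating logistic
functions of voltage,

$$\tau_x(V) = \frac{A}{1 + e^{-k_\tau\,(V_{1/2,\tau} - V)}},$$

with ($A$ ms, $k_\tau$ /mV, $V_{1/2,\tau}$ mV): $m$: $(2, -0.5, -40)$;
$h$: $(40, -0.025, -55)$; $n$: $(55, -0.015, -28)$.  This form — the
standard idiom of stomatogastric conductance-based models — rises toward
its ceiling $A$ with depolarization, so Na activation takes 1–2 ms during
the upstroke.  A pure exponential $\tau = A e^{k_\tau (V - V_{1/2,\tau})}$
with the same constants is retained as a configuration option
(`tau_form = "exponential"`), but it makes $\tau_m$ collapse below a
microsecond a few millivolts above threshold (e-fold per 2 mV); the
resulting front is nearly singular, conduction velocities of 5–8 m/s do not
converge under time-step refinement, and no admissible parameter choice
brings them near the calibration values.  The logistic form converges to
four digits under `dt` halving and reproduces the calibrated velocities, so
it is the default.

**Unprinted parameters.**  Reversal potentials are not part of the source
parameter set; the defaults are the standard $E_{Na} = +50$ mV and
$E_K = -80$ mV (both configuration fields; sensitivity of the calibration
to them is below 3 % across $E_{Na} \in [45, 55]$, $E_K \in [-85, -75]$).
$E_{leak}$ is always *solved* so that the summed membrane current at rest
is exactly zero with all gates at steady state; the membrane then rests
within numerical precision of $-60$ mV at every temperature (tested to
< 0.1 mV over 100 ms).  Gate exponents default to the canonical
Hodgkin–Huxley powers $m^3 h$ and $n^4$ and are configuration fields, not
constants.

**Temperature scaling.**  Each channel property carries its own Q10.  At
axon temperature $T$ the factor
$R = Q_{10}^{(T - 10)/10}$
multiplies maximal conductances ($\bar g(T) = \bar g R$) and divides gate
time constants ($\tau(T) = \tau / R$), relative to the 10 °C baseline where
every $R = 1$.  Scaling applies only outside a short
temperature-insensitive segment at the stimulated end, so temperature can
never alter spike initiation, only propagation.

## Geometry, stimulation and measurement

The cable is 4.075 cm long at 50 µm per compartment (815 compartments).
The first 0.075 cm is the temperature-insensitive stimulated segment — the
excess of the total length over the 4 cm functional projection distance,
which is the one length decomposition consistent with both.  A 1 ms square
current pulse at twice the propagation threshold (found once by bisection
at baseline) enters the first compartment.  Arrival is the first upward
crossing of 0 mV, located to sub-step precision by linear interpolation, at
two sites: 0.5 cm beyond the insensitive segment (0.575 cm) and 1.5 cm
before the sealed distal end (2.575 cm) — far enough from both the stimulus
and the end to avoid initiation and reflection artifacts.

**Velocity convention.**  The physical wave speed is the 2.0 cm inter-site
span over the transit time (`distance = "span"`).  The *reported* velocity
of the package instead attributes the transit to the 4 cm functional
length (`distance = "functional"`, the default), i.e. exactly twice the
span speed under the default geometry.  This convention was adopted by
calibration: it reproduces the reference baseline velocities for the 3 µm
and 6 µm axons to better than 1 %, and it makes the arrival-time
bookkeeping self-consistent — the nominal arrival time over the functional
axon, $4\,\mathrm{cm}/v$, equals the measured transit exactly.  Every
derived statistic in the package (velocity Q10s, delays, robustness
thresholds, ratio analyses) depends on velocity only through such arrival
times or through velocity ratios, and is therefore identical under either
convention; the choice fixes nothing but the printed scale.

**Calibration outcome.**  With the logistic time constants, $m^3h$/$n^4$,
and the default reversals, the baselines are 1.27, 1.80 and 2.54 m/s for 3,
6 and 12 µm.  The first two match their reference values (1.28, 1.8)
within 1 %.  The third cannot: for identical membranes the cable equation
forces $v \propto \sqrt{d}$ (this solver measures a 3 µm → 12 µm ratio of
2.0015), so no parameterization reproduces a 12 µm value of 2.1 alongside
1.28 at 3 µm — that pair of reference values is mutually inconsistent with
the model class itself.  We keep the faithful scaling and report the
discrepancy rather than distorting the model to split the difference.

## Numerical scheme

Time stepping is Crank–Nicolson on the cable term with
NEURON-style staggered gate updates: gates advance analytically
($x \leftarrow x_\infty + (x - x_\infty) e^{-\Delta t / \tau}$, evaluated
at the current voltage), then the voltage solve places the fresh
conductances on the diagonal of the tridiagonal system (Thomas algorithm,
sealed-end boundaries).  The exponential gate update is exact for frozen
voltage and unconditionally stable, which matters because $\tau_m(V)$
spans eight orders of magnitude.  Steady states and rate factors are read
from voltage lookup tables (0.02 mV grid, linear interpolation) built once
per run, keeping the inner loop free of transcendental calls.

Defaults: $\Delta t = 0.0125$ ms, $\Delta x = 50\ \mu m$.  Halving
$\Delta t$ changes the baseline velocity by < 0.5 %, halving $\Delta x$ by
< 1 % (asserted in the suite), and the solver agrees with an independent
stiff-ODE integration of the same semi-discretization (`deSolve::lsoda`,
tolerance $10^{-7}$) to ≲ 0.1 %.

A run is classified *failed* when either recording site never registers an
arrival within the window (three times the baseline transit time): the wave
died out along the cable.  The distal peak voltage is reported so clear-cut
decremental spread (peak below −20 mV) can be told from a marginal
sub-threshold wave.  Numerical instability — non-finite or divergent
voltages, which the implicit scheme makes rare — is flagged separately and
never counted as a biological failure.

## The sweep and its database

`sweep_grid()` enumerates all $4^4 = 256$ combinations of
$Q_{10} \in \{1.5, 2, 3, 4\}$ over $\bar g_{Na}$ (outermost), $\tau_m$,
$\bar g_{leak}$ and $\tau_h$ (innermost), a fixed nesting that defines
`model_index` 0–255; the two Potassium properties stay at 1.5 throughout,
since varying them changes velocity by under 2 %.  `run_sweep()` simulates
every combination at each diameter (3, 6, 12 µm) and temperature (5, 10,
15, 20, 25, 30 °C by default), finds the stimulus threshold once per
diameter, simulates the 10 °C baseline once and broadcasts it (all
temperature factors are 1 there, a degeneracy the suite asserts), and
records failures rather than dropping them.  Chunks can be cached on disk
keyed by a hash of the full configuration, making re-runs idempotent; the
CSV serialization is full-precision and byte-reproducible.

## Timing statistics

For a pair of axons (small diameter model $i$, large diameter model $j$)
at temperature $T$, with arrival times $t = 4\,\mathrm{cm}/v$,

$$\mathrm{delay}_{ij}(T) = \big[t_i(T) - t_i(10)\big] -
                           \big[t_j(T) - t_j(10)\big],$$

positive when the smaller (slower) axon falls behind its baseline timing
relative to the larger one.  The delay is identically zero at baseline and
antisymmetric under exchanging the axons' roles (both asserted over full
256 × 256 matrices).

**Robustness criterion.**  "Temperature-robust" is a delay deviation below
5 % of control.  The source leaves "5 % of what" open; the default
interpretation (`pair_mean_baseline_fraction`) takes 5 % of the mean of the
two axons' baseline arrival times, which evaluates to ≈ 1.34 ms (3 µm vs
6 µm) and ≈ 1.26 ms (3 µm vs 12 µm) — both ≈ the 1.3 ms the study quotes at
20 °C, which is what selected this interpretation.  An explicit
per-temperature absolute-threshold mode is retained for sensitivity
analysis.  Pairs containing a propagation failure are never robust but stay
in the 65,536-pair denominator.

**Ratio analyses.**  Q10 ratios are always larger-axon over smaller-axon;
on the grid they span exactly $[0.375, 8/3]$.  Printed two-decimal bounds
are mapped to their exact grid ratios ($1.33 \to 4/3$, $2.67 \to 8/3$) and
interval membership uses a $10^{-9}$ tolerance so float rounding cannot
misclassify a grid point.  Delay-versus-ratio regressions are ordinary
unweighted least squares over non-failed pairs, one per ordered property
pair per temperature.  Necessity (share of outside-interval pairs that are
non-robust) and sufficiency (share of inside-interval pairs that are
robust) return `NA` with a warning when their denominator is empty — a
vacuous predicate is undefined, not 100 % — and both are cross-checked in
the suite against a brute-force set enumeration on a reduced two-value
grid.  In the high/low composition analysis, a ratio bin achievable by
several (large, small) combinations orders those combinations element-wise
and labels the upper half "high"; this is the only labelling consistent
with both of the study's worked examples (0.75: 3:4 vs 1.5:2; 0.5: 2:4 vs
1.5:3).  The coefficient-of-variation analysis compares the larger axon's
per-property Q10 variability among robust pairs against the CV of the
uniform distribution on $\{1.5, 2, 3, 4\}$ (0.3658).

## The synthetic experimental pipeline

`generate_velocity_dataset()` stands in for multi-animal recordings of
pyloric conduction velocities between 5 and 25 °C.  Each neuron type (PD,
PY, LP) follows a fixed sigmoid temperature response; the printed fit
parameters produce negative values at low temperature if read as velocities
in m/s, but read as $\log_{10}$(velocity) — the same semilog scale on which
the velocity Q10s are defined — they give positive velocities ordered
LP > PD > PY at 10 °C (≈ 0.90, 0.75, 0.59 m/s) with regression Q10s near
1.5, matching the reported axonal temperature sensitivities.  That
self-consistent reading is the default (`scale = "log10"`); a
normalized-velocity-times-baseline mode is available.  Per-animal
variability is multiplicative Gaussian noise (default SD 5 %, a typical
between-preparation spread for such recordings), rectified to keep
velocities positive; the seed is mandatory and travels with the data, and
regeneration is bit-identical.

The generator emulates the *shape* of the measured temperature responses
only.  It does not emulate animal-to-animal variation in the sigmoid
parameters themselves, temperature-dependent failures, or recording noise
correlated across temperatures — so tests passing on synthetic data show
that the estimators and the phase pipeline are correct, not that the
biological effect sizes are recovered from realistic data.

Phase constancy: arrival times at the 4 cm functional distance are
differenced against the pacemaker (PD), divided by the cycle period at that
temperature, and compared with the same quantity at 10 °C, in percent of
cycle.  The measured cycle periods are not available, so the default
`cycle_period_model()` is an explicitly synthetic stand-in — 1 s at 10 °C
with a frequency Q10 of 2, typical for the pyloric rhythm — and the
pipeline accepts a measured period table in its place.  Phase deviations
are invariant under a joint rescaling of velocities and distance (a unit
change); rescaling velocities alone divides them by the same factor, since
the arrival-time differences shrink while the period does not.

## Problem sizes

The acceptance script and the acceptance tests run the full study scale:
256 models × 3 diameters × {5, 10, 15, 20, 30} °C (the temperatures the
headline quantities need), 815 compartments, $\Delta t = 0.0125$ ms —
about 1,900 cable simulations in a few minutes on one core.  Unit tests of
the solver's contracts run on a shortened 1.575 cm cable with the same
compartment size, where each simulation takes tens of milliseconds.

## Known limitations and discrepancies

* **Velocity-response steepness.**  The endpoint velocity-Q10 range of the
  3 µm sweep comes out 0.90–2.73 here against a reference range of ≈ 1–2.3:
  this implementation's velocity responds more steeply to the Q10 scaling,
  at both ends, than the original model did.  E_Na/E_K tuning moves this by
  under 1 %, and thresholds that would reproduce the reference robustness
  counts are inconsistent with the 1.3 ms criterion the study itself
  quotes, so the difference is intrinsic — it must live in unprinted
  details of the original channel implementations.  Because every
  robustness count and coordination percentage derives from this response
  surface, those quantities are systematically offset here (fewer robust
  pairs at 20 °C, more at 30 °C, weaker necessity/sufficiency contrasts),
  while the structural findings they support — τ_m/τ_m as the steepest
  delay predictor, fewer robust pairs for more disparate diameters and
  hotter temperatures, exact ratio bounds — all reproduce.
* **Propagation-failure onset.**  High Na-inactivation and leak Q10s do
  cause propagation failure, but onset sits near 35 °C here rather than
  within the 25–30 °C sweep range, so the 30 °C census lacks failed-pair
  attrition.
* **12 µm baseline.**  See the calibration section: $\sqrt{d}$ scaling is
  exact in this model class, so the 12 µm reference baseline cannot be
  met together with the other two.
* The model is deliberately generic: one uniform cable, no myelination,
  branching, synaptic input, repetitive firing or history-dependent
  conduction, and no neuromodulatory mechanisms.  Conclusions about the
  pyloric system rest on the diameters and velocity differences being in
  its range, not on cell-type-specific channel models.
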