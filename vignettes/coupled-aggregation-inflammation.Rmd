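---
title: "Methods: the coupled aggregation-inflammation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coupled aggregation-inflammation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented in `amyloidosc`, the numerical
and statistical choices behind each analysis layer, and the limits of what
the test suite can establish.

## Model and assumptions

The brain compartment is treated as homogeneous and of fixed volume, valid
for the early disease phase before substantial plaque build-up. Aggregation
follows a nucleation-conversion-elongation scheme with secondary nucleation:
monomers form oligomers by primary nucleation (forward constant `j1`,
monomer order `n1 = 0.8`, reverse constant `j_neg1`); oligomers convert
irreversibly into elongation-competent fibril particles (`j2`, monomer order
`nconv = 2.7`); fibrils elongate by monomer addition (`j3`), which grows
fibril mass but not particle number; and fibril surfaces catalyze new
oligomer formation (`j4`, monomer order `n2 = 0.9`, first order in fibril
mass). Conversion splits the converted mass between the monomer and oligomer
pools with weights `nconv/(1+nconv)` and `1/(1+nconv)`, which makes the
closed system conserve `a_m + a_o + a_f` exactly — an identity the tests
verify both on the right-hand side (1000 random states, absolute residual
below 1e-25 M/s) and through the integrator (relative drift below 1e-4 over
1e7 s).

Turnover and feedback add four processes: zeroth-order monomer generation
`k_plus` (M/s), first-order clearance `k_minus` (1/s) attenuated for
oligomers (`gamma_o = 0.05`) and fibrils (`gamma_f = 0.01`), induction of a
single inflammation variable by oligomer and fibril mass (weights
`delta_o = 8e5`, `delta_f = 2e5`, in a.u. per M per s), and linear
self-limitation of inflammation (`k_infl`). Inflammation feeds back through
a Hill response with half-maximum at `infl_ref` and steepness `steep`,
interpolating each coupled rate between its intrinsic value `c0` and its
saturating value `c_inf`. By default only generation and clearance are
coupled (generation falls to 0, clearance rises fivefold across the
response); the `coupled_rate` mechanism is generic, so any aggregation
constant can be made inflammation-dependent by configuration.

Two conventions deserve a note. The inflammation balance is implemented as a
differential equation, `d(infl)/dt = delta_o a_o + delta_f a_f - k_infl
infl`: an algebraic reading would make the self-limitation constant
meaningless. And `k_minus` carries units of 1/s (first-order clearance); its
default 2.78e-5 is exactly a fractional clearance of 10% per hour.
Inflammation induction weights oligomers by monomer-equivalent mass, not by
particle count; the `infl` scale is arbitrary and is calibrated entirely by
`infl_ref`.

## Numerical integration

The species span 1e-12 to 1e-4 M and the rate constants sixteen orders of
magnitude, so the system is integrated with LSODA (via `deSolve`), with
`rtol = 1e-8`, `atol = 1e-20` M per concentration and `1e-10` for the
inflammation level. Tiny negative excursions (below `atol`) are clamped to
zero inside the right-hand side before the fractional powers are taken,
avoiding complex or NaN values; output samples are clamped likewise. A
trajectory is declared divergent if any component exceeds 1 M. The tests
anchor the solver against an independently coded fixed-step RK4 reference on
a short horizon and check that halving the tolerances moves the final
monomer level by far less than 0.1%.

Output sampling is decoupled from solver stepping. Aggregation analyses use
log-spaced samples (default 500-800 points over 1 s to 1e7 s); oscillation
analyses use a uniform 1 s grid over an analysis window, by default the last
1e5 s of a 1.5e5 s run, with coarse sampling before the window. Storing the
full 1e7-point uniform grid is unnecessary for either analysis and is
avoided for memory reasons.

## Aggregation metrics

The logistic `L / (1 + exp(-k (t - t0)))` is fitted to the fibril mass
*fraction* (`a_f` / initial monomer), which conditions the fit uniformly
across four orders of magnitude in concentration. Starting values are
`L = max(signal)`, `t0` at half-plateau, `k = 4 max(slope)/L`. Because the
fit is performed on log-spaced samples while the natural convention is dense
uniform sampling, residuals are weighted by their trapezoid widths, making
the objective a quadrature of the uniform-in-time squared error; the fitted
constants are then independent of the sampling layout. The aggregation rate
is the growth constant `k` itself, and the lag time is the t-axis intercept
of the inflection tangent, `t0 - 2/k`. Apparent molecular orders come from
ordinary least squares on double-log axes over the 13-concentration ladder
(0.01-100 uM); a 5-point sub-ladder is used as the fast mode. Noiseless
synthetic logistics are recovered to relative error below 1e-6 across
`k` in [1e-5, 1e-1] and `t0` in [1e2, 1e6].

## Oscillation metrics

Oscillations are quantified on the monomer concentration (the clearest
readout; the other variables oscillate in phase with smaller relative
excursions) after a 5e4 s stabilization cutoff. The series is smoothed with
a Gaussian kernel of width `sigma = (log10(n)/2)^2` samples — 6.25 for the
default 1e5-sample window — implemented as an edge-renormalized convolution
so a constant series is preserved exactly and no samples are lost. Peaks are
all strict local maxima of the smoothed series (maximum-sensitivity
detection); troughs are the peaks of the negated series. The period is the
mean spacing of the last five peaks; the baseline is the midpoint between
the mean last-five peak and trough values; the normalized amplitude is the
mean peak-minus-trough excursion divided by the baseline, so a signal
oscillating down to zero attains the supremum of 2.

Regime classification is a package choice where the underlying convention is
qualitative: `steady_oscillation` requires at least five peaks, last-five
cycle amplitudes varying by under 10% relative, and normalized amplitude
above 0.01; otherwise `damped` if any peaks exist, else `monotonic`. The
thresholds were chosen so that decaying transients whose measured amplitude
becomes negligibly small classify as damped. For damped series the period is
still reported but peak spacing can be irregular and should not be
over-interpreted. Slowly relaxing oscillators (periods above ~1e4 s) may
still be settling at the end of the default window and can classify as
damped on that window even when a longer run would show a steady cycle;
widen `t_end` when sweeping into slow-oscillation territory.

## Sweeps and bifurcation location

Sweeps vary one flat parameter key at a time (or the three inflammation
parameters factorially) with all else fixed, re-running the open-coupled
system from zero state per point. Linked rules — for instance keeping
`k_minus_inf = 5 * k_minus_0` along a clearance sweep, or `k_plus_inf = 0`
along a generation sweep — are explicit function objects in the sweep call,
because different analyses use different conventions. Bifurcations are
located purely by simulation: `classify_bifurcation()` returns the grid
intervals where the regime label changes, so a boundary is only ever known
to one grid step. Default test and acceptance grids use 6-10 points per
sweep; the full-resolution grids (200-500 steps) remain available through
the same interface. Per-point integration failures are recorded in the
result rather than aborting the sweep.

## Steady states and sensitivities

`steady_state()` integrates to `t_eval` (default 1e6 s), refuses to report
if the trailing window shows a sustained oscillation, and attaches a
convergence warning when any nonzero component's projected relative drift
`|da/dt| t_eval / a` exceeds 1%. Fibril mass typically still accumulates
slowly at 1e6 s in the open regimes; the monomer and oligomer levels are
settled. Scaled sensitivities use central finite differences with relative
step 1e-3 (second-order accurate without implementing forward sensitivity
equations); halving the step moves the entries by well under 1%. All rate,
attenuation and coupling constants get a column — the `c0` and nonzero
`c_inf` facets separately — but not the kinetic orders. Zero-valued
parameters have no perturbation scale and get sensitivity 0 by convention;
species at zero concentration yield missing entries.

One caveat the analysis surfaced: with the standard coupled values the
settled inflammation level (~0.044) sits below `infl_ref = 0.1`, and at
steepness 50 the Hill response there is numerically zero — the feedback is
disengaged at steady state, and the monomer's sensitivities to generation
and clearance equal their uncoupled values. Homeostatic buffering (markedly
reduced |sensitivity|) appears as soon as the response is engaged at the
fixed point, e.g. at `steep = 4`, `infl_ref = 0.05`, which is how the test
suite demonstrates it.

## Design choices at genuinely open points

- The convergence claim for the open-coupled fixed point is checked on the
  phase-plane scale: endpoints from starts across 0-1.2 uM must agree to
  within 1% of the largest start. Absolute monomer levels cannot agree more
  finely, because fibril particles have no clearance term — `a_fp` is
  monotonically non-decreasing — so runs that aggregate strongly during
  their transient (starts at or above ~0.9 uM) permanently carry more fibril
  particles and a correspondingly larger elongation drain. For the same
  reason the limit-cycle overlap property is exercised for starts up to
  0.6 uM.
- The mild-oscillation working point (`mild_oscillation_params()`: steep 50,
  infl_ref 0.01, k_infl 0.003, generation 7e-12 -> 0) lies very close to the
  Hopf boundary: in this implementation it is weakly damped (normalized
  amplitude ~0.03 on the default window, decaying). Quantities measured at
  or near such a point are extremely sensitive to small parameter or
  convention differences; band-level structure (onset of oscillation near
  `j1 = 1e-7`, loss of oscillation above `gamma_o = 0.2` or
  `k_infl = 3e-3`, amplitude ceilings of 2 and ~1.5-1.7) is far more
  robust and is what the sweeps and tests emphasize.
- Concentrations are micromolar at the user-facing entry points
  (`abeta_preset(m0_uM = )`, the CLI `--m0`) and molar everywhere internally
  and in files, the least-surprise split for this literature.

## What the synthetic checks do and do not show

All inputs are generated in code: synthetic logistics and sinusoids for the
metric layers, and the model's own trajectories for everything else. Passing
tests therefore establish internal correctness — the equations, conservation
laws, fitting and peak-detection conventions, and regime logic — under
noiseless, perfectly sampled conditions. They do not establish that the
model describes real CSF or imaging time series: experimental data would add
measurement noise, irregular sampling, and slow drifts that the logistic and
last-five-peaks estimators are not hardened against, and the inflammation
variable aggregates an entire signalling cascade into one dimension with an
arbitrary scale.

## Problem sizes

The shipped analyses are sized for a desk run: 13 stiff integrations to
1e7 s for the closed-system ladder, single 1.5e5 s windowed runs per
oscillation summary, 6-10 point sweep grids, and steady-state evaluation at
1e6 s; the full test suite and the acceptance script each complete in a few
minutes on one CPU.
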