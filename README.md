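# amyloidosc

Simulation and analysis of a minimal dynamical model that couples
amyloid-β (Aβ) aggregation to neuroinflammation. The package is aimed at
computational and systems biologists studying how the feedback between
protein aggregation and the innate immune response can turn a homeostatic
steady state into sustained biochemical oscillations — a candidate mechanism
for the slow transition from the prodromal to the progressive phase of
Alzheimer's disease — and at anyone who needs a compact, well-tested
nucleation–conversion–elongation aggregation kinetics sandbox in R.

## The model

Five state variables: monomer $a_m$, oligomer $a_o$ (monomer equivalents),
fibril particle number $a_{fp}$, fibril mass $a_f$ (monomer equivalents),
all molar, and a dimensionless inflammation level $infl$:

$$\dot a_m = k_+ - k_- a_m - j_1 a_m^{n1} + j_{-1} a_o
  - \tfrac{nconv}{1+nconv} j_2 a_m^{nconv} a_o - j_3 a_m a_{fp}
  - j_4 a_m^{n2} a_f$$

$$\dot a_o = j_1 a_m^{n1} - j_{-1} a_o
  - \tfrac{1}{1+nconv} j_2 a_m^{nconv} a_o + j_4 a_m^{n2} a_f
  - \gamma_o k_- a_o$$

$$\dot a_{fp} = j_2 a_m^{nconv} a_o, \qquad
  \dot a_f = j_2 a_m^{nconv} a_o + j_3 a_m a_{fp} - \gamma_f k_- a_f$$

$$\dot{infl} = \delta_o a_o + \delta_f a_f - k_{infl}\, infl$$

Generation and clearance respond to inflammation through a Hill function
$resp = infl^{steep}/(infl\_ref^{steep} + infl^{steep})$ and the linear
interpolation $c = c_0 + (c_\infty - c_0)\,resp$, closing a delayed negative
feedback loop: aggregates induce inflammation, inflammation suppresses Aβ
production and boosts clearance.

Three presets cover the study regimes: `closed` (in vitro: no turnover, no
inflammation), `open_uncoupled` (physiological turnover, no feedback) and
`open_coupled` (full feedback). On top of the integrator the package
provides the in vitro observables (logistic fits of fibril growth, lag
times, double-log scaling exponents, oligomer transients, average fibril
length), peak-based oscillation metrics (period and baseline-normalized
amplitude from the last five peaks after a stabilization window, regime
classification), 1-D and 3-parameter bifurcation sweeps, and scaled
steady-state sensitivities $(\partial y/\partial x)(x/y)$.

## Worked example

Closed-system aggregation at three starting concentrations, then the
concentration scaling of the aggregation rate and lag time:

```r
library(amyloidosc)

scan <- aggregation_scan(c(0.1, 1, 10))   # initial monomer, in uM
scan
#>   m0_uM agg_rate_per_s lag_time_s final_avg_length peak_oligomer_pct
#> 1   0.1       2.31e-06     147125           485890              1.71
#> 2   1.0       1.33e-04       8252            74505              2.23
#> 3  10.0       4.45e-03        566            20448              1.43

scaling_exponents(scan, conc = m0_uM)
#>   observable exponent intercept r_squared n_points
#> 1       rate     1.64     -3.95     0.998        3
#> 2        lag    -1.21      3.95     1.000        3
```

Aggregation is faster and the lag shorter at higher concentration; the
slopes on double-log axes are the apparent molecular orders (about +1.6 for
the rate and −1.2 to −1.4 for the lag, depending on the concentration
range). Fibrils grown from dilute monomer end up an order of magnitude
longer than those grown from concentrated monomer, where secondary
nucleation spreads the mass over many more particles.

In the open coupled regime, lowering the inflammation self-regulation
constant and the reference level pushes the system across a Hopf-like
bifurcation into sustained oscillation:

```r
p <- apply_overrides(abeta_preset("open_coupled")$params,
                     list(k_infl = 1e-3, infl_ref = 0.005))
oscillate_abeta(p)
#>   period_s norm_amplitude  baseline n_peaks             regime
#> 1     6422          1.992 7.236e-10      16 steady_oscillation
```

The monomer concentration cycles every ~6400 s with a normalized amplitude
near the theoretical maximum of 2 (peak-minus-trough divided by the
midpoint baseline; 2 means the troughs reach essentially zero).
`sweep_1d()` maps such summaries over a parameter grid and
`classify_bifurcation()` brackets the regime boundaries;
`autoplot()` methods plot trajectories, scans and sweeps.

A thin command-line front end with `simulate`, `aggscan`, `oscillate`,
`sweep`, `grid`, `sensitivity` and `reproduce` subcommands is installed at
`inst/scripts/amyloidosc`.

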