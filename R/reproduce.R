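#' Preset reproduction experiments
#'
#' Canned analyses matching the package's headline figures: the closed-system
#' scaling exponents (`"fig2e"`), the open-uncoupled steady state
#' (`"fig2f"`), and the bifurcation sweeps over `k_infl` (`"fig3b"`),
#' monomer generation `k_plus_0` (`"fig4b"`), primary nucleation `j1`
#' (`"fig4d"`) and oligomer-clearance attenuation `gamma_o` (`"fig4f"`).
#' `fast = TRUE` (default) uses coarse sweep grids and the 5-point
#' concentration sub-ladder; `fast = FALSE` uses the 13-point ladder and
#' finer grids.
#'
#' @param experiment One of `"fig2e"`, `"fig2f"`, `"fig3b"`, `"fig4b"`,
#'   `"fig4d"`, `"fig4f"`.
#' @param fast Coarse-resolution mode (default `TRUE`).
#' @return A tibble; its class depends on the experiment (`scaling_fit`,
#'   steady-state row, or `abeta_sweep`).
#' @export
reproduce_experiment <- function(experiment = c("fig2e", "fig2f", "fig3b",
                                                "fig4b", "fig4d", "fig4f"),
                                 fast = TRUE) {
  experiment <- match.arg(experiment)
  osc_base <- mild_oscillation_params()
  switch(experiment,
    fig2e = {
      conc <- if (fast) c(0.01, 0.1, 1, 10, 100) else abeta_ladder()
      scan <- aggregation_scan(conc)
      scaling_exponents(scan, conc = m0_uM)
    },
    fig2f = steady_state(abeta_preset("open_uncoupled")),
    fig3b = {
      base <- apply_overrides(abeta_preset("open_coupled")$params,
                              list(steep = 50, infl_ref = 0.005,
                                   k_plus_0 = 7e-12, k_plus_inf = 0))
      n <- if (fast) 10L else 50L
      sweep_1d("k_infl", seq(1e-4, 6e-3, length.out = n), base = base)
    },
    fig4b = {
      n <- if (fast) 8L else 40L
      sweep_1d("k_plus_0", 10^seq(log10(2e-10), log10(6e-9), length.out = n),
               base = osc_base, linked = list(k_plus_inf = function(v) 0))
    },
    fig4d = {
      n <- if (fast) 8L else 40L
      sweep_1d("j1", 10^seq(-8, -6, length.out = n), base = osc_base)
    },
    fig4f = {
      n <- if (fast) 10L else 40L
      sweep_1d("gamma_o", 10^seq(-2, 0, length.out = n), base = osc_base)
    })
}

#' Baseline parameters of the mild-oscillation working point
#'
#' The open-coupled parameter set used as the reference point for the
#' aggregation-parameter sweeps: Hill steepness 50, reference inflammation
#' 0.01, inflammation relaxation 0.003, generation 7e-12 -> 0 M/s across the
#' inflammation response, clearance 2.78e-4 -> 1.39e-3 1/s, aggregation
#' constants at their standard values.
#'
#' @return An [abeta_parameters()] object.
#' @export
mild_oscillation_params <- function() {
  apply_overrides(abeta_preset("open_coupled")$params,
                  list(steep = 50, infl_ref = 0.01, k_infl = 0.003,
                       k_plus_0 = 7e-12, k_plus_inf = 0,
                       k_minus_0 = 2.78e-4, k_minus_inf = 1.39e-3))
}
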