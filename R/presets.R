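#' Regime presets: closed, open uncoupled, open coupled
#'
#' The three study regimes of the model, each a full parameter set plus
#' initial state:
#' \describe{
#'   \item{`closed`}{In vitro regime: no generation or clearance
#'     (`k_plus = k_minus = 0`), no inflammation induction
#'     (`delta_o = delta_f = 0`). The caller supplies the initial monomer
#'     concentration `m0_uM`; all aggregate species and inflammation start
#'     at 0.}
#'   \item{`open_uncoupled`}{Physiological turnover without feedback:
#'     generation 1e-12 M/s, clearance 2.78e-5 1/s (10% per hour), no
#'     inflammation induction, all species 0 at t = 0.}
#'   \item{`open_coupled`}{Full in vivo regime with the fast-turnover
#'     generation/clearance pairs (`k_plus` 7.34e-12 -> 0 M/s, `k_minus`
#'     2.78e-4 -> 1.39e-3 1/s across the inflammation response) and
#'     inflammation induction weights `delta_o` = 8e5, `delta_f` = 2e5;
#'     zero initial state.}
#' }
#' Aggregation rate constants are identical across presets.
#'
#' @param name One of `"closed"`, `"open_uncoupled"`, `"open_coupled"`.
#' @param m0_uM Initial monomer concentration in micromolar (converted to M
#'   internally). Default 0.
#' @return A list with elements `params` ([abeta_parameters()]), `init`
#'   (named state vector, molar), and `name`.
#' @examples
#' abeta_preset("closed", m0_uM = 1)$init
#' @export
abeta_preset <- function(name = c("closed", "open_uncoupled", "open_coupled"),
                         m0_uM = 0) {
  if (length(name) != 1L && !identical(name, eval(formals(abeta_preset)$name)))
    abort("`name` must be a single preset name")
  name <- tryCatch(match.arg(name),
                   error = function(e) abort(paste0(
                     "unknown preset `", paste(name, collapse = ","),
                     "`; use closed, open_uncoupled or open_coupled")))
  if (!is.numeric(m0_uM) || length(m0_uM) != 1L || !is.finite(m0_uM) || m0_uM < 0)
    abort("`m0_uM` must be a single non-negative number")
  params <- switch(name,
    closed = abeta_parameters(
      k_plus = coupled_rate(0), k_minus = coupled_rate(0),
      delta_o = 0, delta_f = 0),
    open_uncoupled = abeta_parameters(
      k_plus = coupled_rate(1e-12, 0),
      k_minus = coupled_rate(2.78e-5, 1.39e-4),
      delta_o = 0, delta_f = 0),
    open_coupled = abeta_parameters(
      k_plus = coupled_rate(7.34e-12, 0),
      k_minus = coupled_rate(2.78e-4, 1.39e-3),
      delta_o = 8e5, delta_f = 2e5)
  )
  init <- setNames(c(m0_uM * 1e-6, 0, 0, 0, 0), state_names())
  list(params = params, init = init, name = name)
}

#' Standard initial-concentration ladder for closed-system scans
#'
#' The thirteen initial monomer concentrations (in micromolar) used for the
#' concentration-dependence analysis of closed-system aggregation.
#'
#' @return Numeric vector, 0.01 to 100 uM.
#' @export
abeta_ladder <- function() {
  c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 20, 50, 100)
}
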