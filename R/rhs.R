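#' State variables of the model
#'
#' @return Character vector of the five state names: monomer `a_m`, oligomer
#'   `a_o` (monomer equivalents), fibril particle `a_fp` (number
#'   concentration), fibril mass `a_f` (monomer equivalents) — all molar —
#'   and the dimensionless inflammation level `infl`.
#' @export
state_names <- function() c("a_m", "a_o", "a_fp", "a_f", "infl")

as_state <- function(state) {
  if (is.data.frame(state)) {
    if (nrow(state) != 1L) abort("`state` data frame must have exactly one row")
    state <- unlist(state[state_names()])
  }
  state <- unlist(state)
  if (!is.null(names(state)) && all(state_names() %in% names(state)))
    state <- state[state_names()]
  if (length(state) != 5L) abort("`state` must have five components (a_m, a_o, a_fp, a_f, infl)")
  if (any(!is.finite(state))) abort("`state` must be finite")
  setNames(as.numeric(state), state_names())
}

#' Time derivatives of the five-variable model
#'
#' The right-hand side of the coupled ODE system. Monomers are generated at
#' the inflammation-modulated rate `k_plus`, cleared first-order at `k_minus`,
#' and consumed by primary nucleation (order `n1`), oligomer conversion
#' (monomer share `nconv/(1+nconv)` of the converted mass), elongation, and
#' secondary nucleation (order `n2` in monomer, first order in fibril mass).
#' Oligomers gain from both nucleation routes, lose by reverse nucleation,
#' conversion (share `1/(1+nconv)`) and attenuated clearance. Conversion
#' creates fibril particles; elongation adds fibril mass without changing the
#' particle count; fibril mass is cleared with attenuation `gamma_f`. The
#' inflammation level is driven by oligomer and fibril mass and relaxes at
#' `k_infl`. Components are clamped at 0 before the fractional powers to
#' tolerate tiny negative solver excursions.
#'
#' @param state Named numeric vector (or one-row data frame) with components
#'   `a_m`, `a_o`, `a_fp`, `a_f`, `infl`.
#' @param params An [abeta_parameters()] object.
#' @return Named numeric vector of derivatives (M/s; a.u./s for `infl`).
#' @examples
#' p <- abeta_preset("closed")$params
#' abeta_rhs(c(a_m = 1e-6, a_o = 0, a_fp = 0, a_f = 0, infl = 0), p)
#' @export
abeta_rhs <- function(state, params) {
  stopifnot(inherits(params, "abeta_parameters"))
  y <- as_state(state)
  d <- rhs_closure(params)(0, y, NULL)[[1L]]
  if (any(is.nan(d))) abort("derivative evaluation produced NaN")
  setNames(d, state_names())
}

# Build a fast deSolve-compatible RHS closure; all parameter lookups and the
# coupled/uncoupled decisions are resolved once, outside the solver loop.
rhs_closure <- function(params) {
  gamma_o <- params$gamma_o; gamma_f <- params$gamma_f
  n1 <- params$n1; nconv <- params$nconv; n2 <- params$n2
  delta_o <- params$delta_o; delta_f <- params$delta_f
  k_infl <- params$k_infl; infl_ref <- params$infl_ref; steep <- params$steep
  log_ref <- log(infl_ref)
  cf <- function(x) c(rate_c0(x), rate_cinf(x))
  kp <- cf(params$k_plus);  km <- cf(params$k_minus)
  j1 <- cf(params$j1); jn1 <- cf(params$j_neg1)
  j2 <- cf(params$j2); j3 <- cf(params$j3); j4 <- cf(params$j4)
  any_coupled <- any(c(diff(kp), diff(km), diff(j1), diff(jn1),
                       diff(j2), diff(j3), diff(j4)) != 0)
  pre_m <- nconv / (1 + nconv)
  pre_o <- 1 / (1 + nconv)

  function(t, y, parms) {
    a_m <- max(y[1L], 0); a_o <- max(y[2L], 0); a_fp <- max(y[3L], 0)
    a_f <- max(y[4L], 0); infl <- max(y[5L], 0)
    if (any_coupled && infl > 0) {
      resp <- 1 / (1 + exp(steep * (log_ref - log(infl))))
    } else resp <- 0
    k_plus  <- kp[1L] + (kp[2L] - kp[1L]) * resp
    k_minus <- km[1L] + (km[2L] - km[1L]) * resp
    v_j1  <- j1[1L]  + (j1[2L]  - j1[1L])  * resp
    v_jn1 <- jn1[1L] + (jn1[2L] - jn1[1L]) * resp
    v_j2  <- j2[1L]  + (j2[2L]  - j2[1L])  * resp
    v_j3  <- j3[1L]  + (j3[2L]  - j3[1L])  * resp
    v_j4  <- j4[1L]  + (j4[2L]  - j4[1L])  * resp

    nuc1  <- v_j1 * a_m^n1
    rev1  <- v_jn1 * a_o
    conv  <- v_j2 * a_m^nconv * a_o
    elong <- v_j3 * a_m * a_fp
    nuc2  <- v_j4 * a_m^n2 * a_f

    list(c(
      k_plus - k_minus * a_m - nuc1 + rev1 - pre_m * conv - elong - nuc2,
      nuc1 - rev1 - pre_o * conv + nuc2 - gamma_o * k_minus * a_o,
      conv,
      conv + elong - gamma_f * k_minus * a_f,
      delta_o * a_o + delta_f * a_f - k_infl * infl
    ))
  }
}
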