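#' Inflammation-coupled rate constant
#'
#' A kinetic parameter whose value interpolates linearly between `c0` (no
#' inflammation) and `c_inf` (saturating inflammation) as the Hill response
#' moves from 0 to 1. A rate with `c0 == c_inf` is inflammation-independent.
#'
#' @param c0 Rate value at zero inflammation (units of the underlying rate).
#' @param c_inf Rate value in the limit of infinite inflammation. Defaults to
#'   `c0`, i.e. an uncoupled rate.
#' @return An object of class `coupled_rate`.
#' @examples
#' coupled_rate(2.78e-4, 1.39e-3)
#' @export
coupled_rate <- function(c0, c_inf = c0) {
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 < 0)
    abort("`c0` must be a single finite non-negative number.")
  if (!is.numeric(c_inf) || length(c_inf) != 1L || !is.finite(c_inf) || c_inf < 0)
    abort("`c_inf` must be a single finite non-negative number.")
  structure(list(c0 = c0, c_inf = c_inf), class = "coupled_rate")
}

#' @export
print.coupled_rate <- function(x, ...) {
  cat(sprintf("<coupled_rate> c0 = %g, c_inf = %g%s\n", x$c0, x$c_inf,
              if (x$c0 == x$c_inf) " (uncoupled)" else ""))
  invisible(x)
}

is_coupled_rate <- function(x) inherits(x, "coupled_rate")

#' Hill-type inflammation response
#'
#' Sigmoidal map from the inflammation level to a modulation factor in
#' \eqn{[0, 1]}: \eqn{resp = infl^{steep} / (infl\_ref^{steep} + infl^{steep})}.
#' The response is exactly 0 at `infl = 0`, 0.5 at `infl = infl_ref`, and tends
#' to 1 as `infl` grows. Computed on the log scale so that very steep responses
#' (the default steepness is 50) neither overflow nor underflow.
#'
#' @param infl Inflammation level (dimensionless, non-negative); vectorized.
#' @param infl_ref Reference inflammation level at half-maximal response (> 0).
#' @param steep Hill steepness (> 0).
#' @return Numeric vector of responses in `[0, 1]`.
#' @examples
#' hill_response(c(0, 0.1, 0.2), infl_ref = 0.1, steep = 50)
#' @export
hill_response <- function(infl, infl_ref, steep) {
  if (!is.numeric(infl) || any(!is.finite(infl)) || any(infl < 0))
    abort("`infl` must be finite and non-negative.")
  if (!is.numeric(infl_ref) || length(infl_ref) != 1L || !is.finite(infl_ref) || infl_ref <= 0)
    abort("`infl_ref` must be a single positive number.")
  if (!is.numeric(steep) || length(steep) != 1L || !is.finite(steep) || steep <= 0)
    abort("`steep` must be a single positive number.")
  out <- numeric(length(infl))
  pos <- infl > 0
  # 1 / (1 + (infl_ref/infl)^steep), stable for steep ~ 50
  z <- exp(steep * (log(infl_ref) - log(infl[pos])))
  out[pos] <- 1 / (1 + z)
  out
}

#' Effective value of an inflammation-coupled rate
#'
#' Linear interpolation \eqn{c = c_0 + (c_\infty - c_0)\,resp} between the
#' intrinsic value and the saturating value of a kinetic parameter.
#'
#' @param rate A [coupled_rate()] (a plain number is treated as uncoupled).
#' @param resp Response value(s) in `[0, 1]`, e.g. from [hill_response()].
#' @return Numeric effective rate(s), always between `c0` and `c_inf`.
#' @examples
#' effective_rate(coupled_rate(2.78e-4, 1.39e-3), resp = 0.5)
#' @export
effective_rate <- function(rate, resp) {
  if (!is.numeric(resp) || any(!is.finite(resp)) || any(resp < 0) || any(resp > 1))
    abort("`resp` must lie in [0, 1].")
  if (!is_coupled_rate(rate)) {
    if (!is.numeric(rate) || length(rate) != 1L)
      abort("`rate` must be a coupled_rate or a single number.")
    return(rep(rate, length.out = length(resp)))
  }
  rate$c0 + (rate$c_inf - rate$c0) * resp
}

rate_c0 <- function(x) if (is_coupled_rate(x)) x$c0 else x
rate_cinf <- function(x) if (is_coupled_rate(x)) x$c_inf else x

# parameters that may carry a c0/c_inf pair
.coupled_keys <- c("k_plus", "k_minus", "j1", "j_neg1", "j2", "j3", "j4")
# plain scalar parameters
.scalar_keys <- c("gamma_o", "gamma_f", "n1", "nconv", "n2", "j_neg2", "j_neg3",
                  "j_neg4", "delta_o", "delta_f", "k_infl", "infl_ref", "steep")

#' Kinetic and coupling parameters of the aggregation-inflammation model
#'
#' Builds the full parameter set of the five-variable model. Defaults are the
#' standard in vivo values: concentrations in molar, time in seconds, the
#' inflammation level dimensionless. Monomer generation (`k_plus`, M/s) and
#' first-order clearance (`k_minus`, 1/s) are inflammation-coupled
#' ([coupled_rate()] pairs); the aggregation rate constants may optionally be
#' made coupled as well and are uncoupled by default. The reverse constants of
#' conversion, elongation and secondary nucleation (`j_neg2`, `j_neg3`,
#' `j_neg4`) are structurally zero: these steps are irreversible in the model.
#'
#' @param k_plus Monomer generation rate (M/s), a [coupled_rate()] or number.
#' @param k_minus Monomer clearance rate constant (1/s), [coupled_rate()] or
#'   number. Oligomer and fibril clearance use the same effective constant
#'   attenuated by `gamma_o` and `gamma_f`.
#' @param gamma_o,gamma_f Clearance attenuation factors for oligomers and
#'   fibrils (dimensionless, 0-1 typical).
#' @param j1,j_neg1 Primary nucleation forward / reverse rate constants.
#' @param n1 Monomer kinetic order of primary nucleation.
#' @param j2 Oligomer conversion forward rate constant.
#' @param nconv Monomer kinetic order of conversion.
#' @param j3 Elongation forward rate constant.
#' @param j4 Secondary nucleation forward rate constant.
#' @param n2 Monomer kinetic order of secondary nucleation.
#' @param delta_o,delta_f Inflammation induction weights of oligomers and
#'   fibrils (a.u. per M per s).
#' @param k_infl Inflammation auto-regulation (self-limiting) constant (1/s).
#' @param infl_ref Reference inflammation level of the Hill response (> 0).
#' @param steep Hill steepness (> 0).
#' @param j_neg2,j_neg3,j_neg4 Reverse constants, fixed at 0.
#' @return An object of class `abeta_parameters` (a named list).
#' @seealso [abeta_preset()] for the closed / open-uncoupled / open-coupled
#'   regime presets, [tidy.abeta_parameters()] for a tabular view.
#' @examples
#' p <- abeta_parameters(k_infl = 0.003, infl_ref = 0.01)
#' tidy(p)
#' @export
abeta_parameters <- function(k_plus = coupled_rate(1e-12, 0),
                             k_minus = coupled_rate(2.78e-5, 1.39e-4),
                             gamma_o = 0.05,
                             gamma_f = 0.01,
                             j1 = 6.7e-8,
                             j_neg1 = 9.7e-5,
                             n1 = 0.8,
                             j2 = 1.9e9,
                             nconv = 2.7,
                             j3 = 6.0e6,
                             j4 = 2,
                             n2 = 0.9,
                             delta_o = 8e5,
                             delta_f = 2e5,
                             k_infl = 0.01,
                             infl_ref = 0.1,
                             steep = 50,
                             j_neg2 = 0, j_neg3 = 0, j_neg4 = 0) {
  p <- structure(
    list(k_plus = k_plus, k_minus = k_minus, gamma_o = gamma_o,
         gamma_f = gamma_f, j1 = j1, j_neg1 = j_neg1, n1 = n1, j2 = j2,
         j_neg2 = j_neg2, nconv = nconv, j3 = j3, j_neg3 = j_neg3, j4 = j4,
         j_neg4 = j_neg4, n2 = n2, delta_o = delta_o, delta_f = delta_f,
         k_infl = k_infl, infl_ref = infl_ref, steep = steep),
    class = "abeta_parameters")
  validate_parameters(p)
}

#' @export
print.abeta_parameters <- function(x, ...) {
  cat("<abeta_parameters>\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

validate_parameters <- function(p) {
  for (key in c(.coupled_keys, .scalar_keys)) {
    v <- p[[key]]
    if (is.null(v)) abort(paste0("missing parameter `", key, "`"))
    vals <- if (is_coupled_rate(v)) c(v$c0, v$c_inf) else v
    if (!is.numeric(vals) || any(!is.finite(vals)))
      abort(paste0("parameter `", key, "` must be finite numeric"))
    if (any(vals < 0))
      abort(paste0("parameter `", key, "` must be non-negative"))
  }
  for (key in c("n1", "nconv", "n2", "infl_ref", "steep"))
    if (rate_c0(p[[key]]) <= 0)
      abort(paste0("parameter `", key, "` must be positive"))
  for (key in c("j_neg2", "j_neg3", "j_neg4"))
    if (!identical(rate_c0(p[[key]]), 0) && rate_c0(p[[key]]) != 0)
      abort(paste0("`", key, "` is structurally zero: conversion, elongation and secondary nucleation are irreversible"))
  p
}

#' Flat parameter keys accepted by overrides and sweeps
#'
#' Coupled rates expose `<name>_0` and `<name>_inf` facets in addition to the
#' bare name (which sets both facets at once, i.e. an uncoupled value).
#'
#' @return Character vector of valid keys.
#' @export
param_keys <- function() {
  c(.scalar_keys,
    .coupled_keys,
    paste0(.coupled_keys, "_0"),
    paste0(.coupled_keys, "_inf"))
}

#' Set one parameter by flat key
#'
#' @param params An [abeta_parameters()] object.
#' @param key One of [param_keys()], e.g. `"gamma_o"`, `"k_plus_0"`,
#'   `"k_minus_inf"`. A bare coupled-rate name (e.g. `"j1"`) sets both facets.
#' @param value New numeric value.
#' @return Updated `abeta_parameters`.
#' @export
set_param <- function(params, key, value) {
  stopifnot(inherits(params, "abeta_parameters"))
  if (!is.numeric(value) || length(value) != 1L)
    abort(paste0("value for `", key, "` must be a single number"))
  if (key %in% .scalar_keys) {
    params[[key]] <- value
  } else if (key %in% .coupled_keys) {
    params[[key]] <- if (is_coupled_rate(params[[key]]))
      coupled_rate(value, value) else value
  } else if (grepl("_0$", key) && sub("_0$", "", key) %in% .coupled_keys) {
    base <- sub("_0$", "", key)
    old <- params[[base]]
    params[[base]] <- coupled_rate(value, rate_cinf(old))
  } else if (grepl("_inf$", key) && sub("_inf$", "", key) %in% .coupled_keys) {
    base <- sub("_inf$", "", key)
    old <- params[[base]]
    params[[base]] <- coupled_rate(rate_c0(old), value)
  } else {
    abort(paste0("unknown parameter key `", key, "`; see param_keys()"))
  }
  validate_parameters(params)
}

#' Get one parameter by flat key
#' @inheritParams set_param
#' @return A single numeric value.
#' @export
get_param <- function(params, key) {
  if (key %in% .scalar_keys) return(rate_c0(params[[key]]))
  if (key %in% .coupled_keys) return(rate_c0(params[[key]]))
  if (grepl("_0$", key)) return(rate_c0(params[[sub("_0$", "", key)]]))
  if (grepl("_inf$", key)) return(rate_cinf(params[[sub("_inf$", "", key)]]))
  abort(paste0("unknown parameter key `", key, "`"))
}

#' Apply a named list of flat-key overrides
#'
#' @param params An [abeta_parameters()] object.
#' @param overrides Named list or vector, names from [param_keys()].
#' @return Updated `abeta_parameters`. Unknown keys raise an error naming the
#'   offending key.
#' @export
apply_overrides <- function(params, overrides) {
  if (length(overrides) == 0L) return(params)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    abort("overrides must be a fully named list")
  for (key in names(overrides))
    params <- set_param(params, key, as.numeric(overrides[[key]]))
  params
}

#' @describeIn abeta_parameters Tabular (long) view: one row per flat key, with
#'   coupled rates expanded into their `_0` and `_inf` facets.
#' @param x An `abeta_parameters` object.
#' @param ... Unused.
#' @export
tidy.abeta_parameters <- function(x, ...) {
  rows <- purrr::map(names(unclass(x)), function(key) {
    v <- x[[key]]
    if (is_coupled_rate(v)) {
      tibble(parameter = paste0(key, c("_0", "_inf")),
             value = c(v$c0, v$c_inf))
    } else {
      tibble(parameter = key, value = v)
    }
  })
  dplyr::bind_rows(rows)
}
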