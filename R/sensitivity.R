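#' Non-oscillatory steady state
#'
#' Integrates from zero state (or a supplied state) to `t_eval` and returns
#' the state there, after checking that the trailing window is not in a
#' steady-oscillation regime (a steady state is undefined on a limit cycle)
#' and that each nonzero component has settled: the projected relative drift
#' `|da/dt| * t_eval / a` must stay below 1%, otherwise a convergence warning
#' is attached.
#'
#' @param params Parameters or preset (see [simulate_abeta()]).
#' @param t_eval Evaluation time in seconds (default 1e6).
#' @param init Optional initial state (default zero).
#' @return One-row tibble with the five state columns, `time`, and a logical
#'   `settled`; the full parameters are attached as attribute `params`.
#' @examples
#' \donttest{
#' steady_state(abeta_preset("open_uncoupled"))$a_m * 1e9  # nM
#' }
#' @export
steady_state <- function(params, t_eval = 1e6, init = NULL) {
  # trailing 10% window, sampled coarsely; enough to detect sustained cycles
  w0 <- 0.9 * t_eval
  dt <- max(1, round(t_eval / 1e5))
  tc <- simulate_abeta(params, init = init, t_end = t_eval,
                       sampling = "window", dt = dt, window_start = w0)
  osc <- summarize_oscillation(tc, stabilization_s = w0)
  if (identical(osc$regime, "steady_oscillation"))
    abort(sprintf(paste0("steady state undefined: sustained oscillation ",
                         "(period %.3g s, amplitude %.3g) at t = %g s"),
                  osc$period_s, osc$norm_amplitude, t_eval))
  last <- dplyr::slice_tail(as_tibble(tc), n = 1)
  p <- if (inherits(params, "abeta_parameters")) params else params$params
  dd <- abeta_rhs(last[, state_names()], p)
  st <- unlist(last[, state_names()])
  rel <- abs(dd) * t_eval / pmax(st, .Machine$double.xmin)
  settled <- all(rel[st > 0] < 0.01)
  if (!settled)
    warn(sprintf("state not fully settled at t = %g s (max projected drift %.2g)",
                 t_eval, max(rel[st > 0])))
  out <- dplyr::bind_cols(last[, state_names()],
                          tibble(time = t_eval, settled = settled))
  attr(out, "params") <- p
  out
}

# parameters eligible for sensitivity columns: rate, attenuation and coupling
# constants, excluding the kinetic orders
.sensitivity_keys <- function(params) {
  keys <- c("k_plus_0", "k_plus_inf", "k_minus_0", "k_minus_inf",
            "gamma_o", "gamma_f", "j1", "j_neg1", "j2", "j3", "j4",
            "delta_o", "delta_f", "k_infl", "infl_ref", "steep")
  keys
}

#' Scaled steady-state sensitivities
#'
#' Dimensionless elasticities \eqn{(\partial y/\partial x)(x/y)} of every
#' steady-state concentration with respect to every rate, attenuation and
#' coupling constant (kinetic orders excluded), computed by central finite
#' differences: each parameter is perturbed to \eqn{x (1 \pm rel\_step)}, the
#' steady state recomputed, and the scaled slope formed. Parameters with
#' value zero have no perturbation scale and get sensitivity 0 by convention;
#' entries where the species concentration is zero are `NA`. For coupled
#' rates the `c0` and (nonzero) `c_inf` facets are separate columns.
#'
#' @param params Parameters or preset.
#' @param rel_step Relative perturbation (default 1e-3).
#' @param t_eval Steady-state evaluation time (default 1e6 s).
#' @param keys Optional subset of parameter columns to compute (default: all
#'   eligible constants).
#' @return Long tibble of class `abeta_sensitivity`: `species`, `parameter`,
#'   `sensitivity`, with attributes `eval_time`, `rel_step`, `steady_state`.
#' @examples
#' \donttest{
#' p <- abeta_preset("open_uncoupled")$params
#' p <- apply_overrides(p, list(j1 = 0, j2 = 0, j3 = 0, j4 = 0))
#' s <- scaled_sensitivities(p)
#' dplyr::filter(s, species == "a_m", parameter %in% c("k_plus_0", "k_minus_0"))
#' }
#' @export
scaled_sensitivities <- function(params, rel_step = 1e-3, t_eval = 1e6,
                                 keys = NULL) {
  p <- if (inherits(params, "abeta_parameters")) params else params$params
  ss0 <- suppressWarnings(steady_state(p, t_eval = t_eval))
  y0 <- unlist(ss0[, state_names()])
  keys <- keys %||% .sensitivity_keys(p)
  rows <- purrr::map(keys, function(key) {
    x <- get_param(p, key)
    if (x == 0) {
      return(tibble(species = state_names(), parameter = key, sensitivity = 0))
    }
    res <- tryCatch({
      up <- unlist(suppressWarnings(
        steady_state(set_param(p, key, x * (1 + rel_step)),
                     t_eval = t_eval))[, state_names()])
      dn <- unlist(suppressWarnings(
        steady_state(set_param(p, key, x * (1 - rel_step)),
                     t_eval = t_eval))[, state_names()])
      sens <- ifelse(y0 > 0, (up - dn) / (2 * rel_step * y0), NA_real_)
      tibble(species = state_names(), parameter = key,
             sensitivity = as.numeric(sens))
    }, error = function(e) {
      tibble(species = state_names(), parameter = key,
             sensitivity = NA_real_)
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "eval_time") <- t_eval
  attr(out, "rel_step") <- rel_step
  attr(out, "steady_state") <- ss0
  class(out) <- c("abeta_sensitivity", class(out))
  out
}

#' Write a sensitivity matrix as CSV
#'
#' Wide matrix (rows = species, columns = parameters) preceded by a `#`
#' metadata header block recording the evaluation time and step.
#'
#' @param sens An `abeta_sensitivity` result.
#' @param path Output path.
#' @param preset Optional preset label recorded in the header.
#' @return `path`, invisibly.
#' @export
write_sensitivity_matrix <- function(sens, path, preset = NA_character_) {
  wide <- tidyr::pivot_wider(as_tibble(sens), names_from = "parameter",
                             values_from = "sensitivity")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# eval_time_s: %g", attr(sens, "eval_time")),
               sprintf("# rel_step: %g", attr(sens, "rel_step")),
               sprintf("# preset: %s", preset)), con)
  utils::write.csv(as.data.frame(wide), con, row.names = FALSE)
  invisible(path)
}
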