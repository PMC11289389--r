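#' Integrate the model over time
#'
#' Solves the stiff five-variable system with an adaptive implicit solver
#' (LSODA via \pkg{deSolve}) and returns a sampled trajectory. Two sampling
#' plans cover the two analysis styles: `"log"` (log-spaced samples, for
#' aggregation kinetics spanning 1 to 1e7 s) and `"window"` (coarse sampling
#' up to `window_start`, then a uniform `dt` grid to `t_end`, for oscillation
#' analysis; the default window is the last 1e5 s of a 1.5e5 s run). `"uniform"`
#' samples the whole horizon at `dt`. Output sampling only selects reporting
#' times; solver steps are chosen adaptively to the tolerances either way.
#'
#' @param params An [abeta_parameters()] object, or a preset list from
#'   [abeta_preset()] (its initial state is used unless `init` is given).
#' @param init Initial state: named vector with `a_m`, `a_o`, `a_fp`, `a_f`,
#'   `infl` (molar; `infl` dimensionless). Defaults to all zero.
#' @param t_end Simulation horizon in seconds. `t_end = 0` returns the initial
#'   state as a single-row trajectory.
#' @param sampling `"log"`, `"uniform"` or `"window"`.
#' @param n Number of log-spaced samples (sampling = "log").
#' @param dt Uniform sampling interval in seconds (default 1).
#' @param window_start Start of the uniform window (sampling = "window"),
#'   default 5e4 s.
#' @param rtol Relative solver tolerance (default 1e-8).
#' @param atol Absolute tolerance for the molar species (default 1e-20 M).
#' @param atol_infl Absolute tolerance for the inflammation level (1e-10).
#' @return A tibble of class `abeta_tc` with columns `time`, `a_m`, `a_o`,
#'   `a_fp`, `a_f`, `infl`; the parameters, preset name and solver diagnostics
#'   are attached as attributes. Sampled concentrations are clamped at 0.
#' @examples
#' tc <- simulate_abeta(abeta_preset("closed", m0_uM = 1), t_end = 1e5,
#'                      sampling = "log", n = 100)
#' dplyr::last(tc$a_f)
#' @export
simulate_abeta <- function(params, init = NULL, t_end = 1e7,
                           sampling = c("log", "uniform", "window"),
                           n = 500, dt = 1, window_start = 5e4,
                           rtol = 1e-8, atol = 1e-20, atol_infl = 1e-10) {
  preset_name <- NA_character_
  if (is.list(params) && !inherits(params, "abeta_parameters") &&
      all(c("params", "init") %in% names(params))) {
    if (is.null(init)) init <- params$init
    preset_name <- params$name %||% NA_character_
    params <- params$params
  }
  stopifnot(inherits(params, "abeta_parameters"))
  sampling <- match.arg(sampling)
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) || t_end < 0)
    abort("`t_end` must be a single non-negative number")
  y0 <- if (is.null(init)) setNames(numeric(5L), state_names()) else as_state(init)
  if (any(y0 < 0)) abort("initial state must be non-negative")

  if (t_end == 0) {
    out <- tibble(time = 0, a_m = y0[["a_m"]], a_o = y0[["a_o"]],
                  a_fp = y0[["a_fp"]], a_f = y0[["a_f"]], infl = y0[["infl"]])
    return(new_abeta_tc(out, params, preset_name, diagnostics = NULL))
  }

  times <- switch(sampling,
    log = {
      hi <- log10(t_end)
      unique(c(0, 10^seq(min(0, hi), hi, length.out = n)))
    },
    uniform = seq(0, t_end, by = dt),
    window = {
      if (window_start >= t_end) abort("`window_start` must be below `t_end`")
      pre <- seq(0, window_start, length.out = 201L)
      unique(c(pre[-length(pre)], seq(window_start, t_end, by = dt)))
    })

  res <- withCallingHandlers(
    deSolve::ode(y = y0, times = times, func = rhs_closure(params), parms = NULL,
                 method = "lsoda", rtol = rtol,
                 atol = c(rep(atol, 4L), atol_infl), maxsteps = 100000L),
    warning = function(w) invokeRestart("muffleWarning"))

  if (nrow(res) < length(times)) {
    abort(sprintf("integration failed at t = %.6g s (solver did not converge)",
                  res[nrow(res), 1L]))
  }
  conc <- res[, 2:5]
  if (any(conc > 1))
    abort(sprintf("state blow-up: concentration exceeded 1 M at t = %.6g s",
                  res[which(rowSums(conc > 1) > 0)[1L], 1L]))

  diag <- attributes(res)[c("istate", "rstate")]
  out <- tibble(
    time = res[, 1L],
    a_m  = pmax(res[, 2L], 0),
    a_o  = pmax(res[, 3L], 0),
    a_fp = pmax(res[, 4L], 0),
    a_f  = pmax(res[, 5L], 0),
    infl = pmax(res[, 6L], 0))
  new_abeta_tc(out, params, preset_name, diag)
}

new_abeta_tc <- function(tbl, params, preset_name, diagnostics) {
  structure(tbl,
            params = params,
            preset_name = preset_name,
            diagnostics = diagnostics,
            class = c("abeta_tc", class(tbl)))
}

#' Parameters attached to a trajectory
#' @param tc An `abeta_tc` trajectory.
#' @return The [abeta_parameters()] used to produce it.
#' @export
tc_params <- function(tc) attr(tc, "params")

#' Write / read a trajectory as delimited text
#'
#' Full double precision (`%.17g`), so that a written trajectory re-reads
#' bit-identically. Header: `time_s,a_m_M,a_o_M,a_fp_M,a_f_M,infl`.
#'
#' @param tc An `abeta_tc` trajectory (any data frame with the six columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  cols <- c("time", "a_m", "a_o", "a_fp", "a_f", "infl")
  stopifnot(all(cols %in% names(tc)))
  header <- "time_s,a_m_M,a_o_M,a_fp_M,a_f_M,infl"
  body <- do.call(sprintf, c(list("%.17g,%.17g,%.17g,%.17g,%.17g,%.17g"),
                             lapply(cols, function(cc) tc[[cc]])))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_timecourse
#' @return For `read_timecourse`, a tibble with columns `time`, `a_m`, `a_o`,
#'   `a_fp`, `a_f`, `infl`.
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path)
  names(df) <- c("time", "a_m", "a_o", "a_fp", "a_f", "infl")
  as_tibble(df)
}

#' @export
autoplot.abeta_tc <- function(object, species = c("a_m", "a_o", "a_f"),
                              log_time = TRUE, ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[, c("time", species)],
                              -"time", names_to = "species",
                              values_to = "concentration")
  gg <- ggplot2::ggplot(dplyr::filter(long, .data$time > 0 | !log_time),
                        ggplot2::aes(.data$time, .data$concentration,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "concentration (M)")
  if (log_time) gg <- gg + ggplot2::scale_x_log10()
  gg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
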