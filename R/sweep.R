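#' One-dimensional bifurcation sweep
#'
#' Varies a single parameter (flat key, see [param_keys()]) over a grid,
#' simulates the open-coupled system from zero state at each value, and
#' attaches the oscillation summary per point. Linked-parameter rules (e.g.
#' clearance saturation tied to its intrinsic value, `k_minus_inf = 5 *
#' k_minus_0`) are explicit functions of the swept value rather than hidden
#' conventions. Failures at individual grid points are recorded in the
#' result, not fatal; the sweep errors only if more than half the points
#' fail.
#'
#' @param param Flat parameter key to vary (e.g. `"k_infl"`, `"k_plus_0"`,
#'   `"gamma_o"`).
#' @param values Numeric grid of parameter values (non-empty, finite).
#' @param base Base parameters or preset (default: open-coupled preset).
#' @param linked Optional named list of functions; each is called with the
#'   swept value and its result assigned to the named flat key, e.g.
#'   `list(k_minus_inf = function(v) 5 * v)`.
#' @param field State variable analyzed (default `"a_m"`).
#' @param t_end,stabilization_s,dt Simulation window controls, as in
#'   [oscillate_abeta()].
#' @param keep_traces If `TRUE`, store the analysis-window trace per point in
#'   a list column `trace`.
#' @return A tibble of class `abeta_sweep`: columns `param`, `value`,
#'   `period_s`, `norm_amplitude`, `baseline`, `n_peaks`, `regime`, `ok`,
#'   `message` (and `trace` if requested).
#' @examples
#' \donttest{
#' sw <- sweep_1d("gamma_o", c(0.05, 0.5),
#'                base = abeta_preset("open_coupled"))
#' }
#' @export
sweep_1d <- function(param, values, base = abeta_preset("open_coupled"),
                     linked = NULL, field = "a_m", t_end = 1.5e5,
                     stabilization_s = 5e4, dt = 1, keep_traces = FALSE) {
  if (length(values) == 0L || any(!is.finite(values)))
    abort("`values` must be a non-empty finite numeric grid")
  base_params <- if (inherits(base, "abeta_parameters")) base else base$params
  rows <- purrr::map(values, function(v) {
    res <- tryCatch({
      p <- set_param(base_params, param, v)
      if (!is.null(linked))
        for (key in names(linked)) p <- set_param(p, key, linked[[key]](v))
      tc <- simulate_abeta(p, t_end = t_end, sampling = "window", dt = dt,
                           window_start = stabilization_s)
      s <- summarize_oscillation(tc, field = field,
                                 stabilization_s = stabilization_s)
      s$trace <- if (keep_traces)
        list(as_tibble(tc)[, c("time", field)]) else list(NULL)
      s$ok <- TRUE; s$message <- NA_character_
      s
    }, error = function(e) {
      tibble(period_s = NA_real_, norm_amplitude = NA_real_,
             baseline = NA_real_, n_peaks = NA_integer_,
             regime = NA_character_, trace = list(NULL), ok = FALSE,
             message = conditionMessage(e))
    })
    dplyr::bind_cols(tibble(param = param, value = v), res)
  })
  out <- dplyr::bind_rows(rows)
  if (!keep_traces) out$trace <- NULL
  if (mean(out$ok) < 0.5)
    abort(sprintf("sweep of `%s` failed at %d of %d grid points",
                  param, sum(!out$ok), nrow(out)))
  class(out) <- c("abeta_sweep", class(out))
  out
}

#' Three-parameter oscillation grid
#'
#' Full factorial sweep over the inflammation-response parameters `k_infl`,
#' `steep` and `infl_ref`, each cell an open-coupled run from zero state with
#' its oscillation summary (and optionally the monomer window trace for
#' contour maps).
#'
#' @param k_infl,steep,infl_ref Numeric grids for the three parameters.
#' @inheritParams sweep_1d
#' @param max_cells Guard on the grid size (default 10000).
#' @return A tibble of class `abeta_grid3`: one row per cell with the three
#'   parameter columns plus the oscillation summary (and `trace` list column
#'   if requested).
#' @export
sweep_grid3 <- function(k_infl, steep, infl_ref,
                        base = abeta_preset("open_coupled"), field = "a_m",
                        t_end = 1.5e5, stabilization_s = 5e4, dt = 1,
                        keep_traces = FALSE, max_cells = 10000L) {
  grid <- tidyr::expand_grid(steep = steep, infl_ref = infl_ref,
                             k_infl = k_infl)
  if (nrow(grid) > max_cells)
    abort(sprintf("grid has %d cells, above the budget of %d", nrow(grid),
                  max_cells))
  base_params <- if (inherits(base, "abeta_parameters")) base else base$params
  rows <- purrr::pmap(grid, function(steep, infl_ref, k_infl) {
    res <- tryCatch({
      p <- set_param(base_params, "k_infl", k_infl)
      p <- set_param(p, "steep", steep)
      p <- set_param(p, "infl_ref", infl_ref)
      tc <- simulate_abeta(p, t_end = t_end, sampling = "window", dt = dt,
                           window_start = stabilization_s)
      s <- summarize_oscillation(tc, field = field,
                                 stabilization_s = stabilization_s)
      s$trace <- if (keep_traces)
        list(as_tibble(tc)[, c("time", field)]) else list(NULL)
      s$ok <- TRUE; s$message <- NA_character_
      s
    }, error = function(e) {
      tibble(period_s = NA_real_, norm_amplitude = NA_real_,
             baseline = NA_real_, n_peaks = NA_integer_,
             regime = NA_character_, trace = list(NULL), ok = FALSE,
             message = conditionMessage(e))
    })
    dplyr::bind_cols(tibble(steep = steep, infl_ref = infl_ref,
                            k_infl = k_infl), res)
  })
  out <- dplyr::bind_rows(rows)
  if (!keep_traces) out$trace <- NULL
  class(out) <- c("abeta_grid3", class(out))
  out
}

#' Regime-transition boundaries of a sweep
#'
#' Scans adjacent grid points of a 1-D sweep for changes of oscillation
#' regime and returns the bracketing parameter intervals (the simulation
#' locates bifurcations only up to the grid resolution).
#'
#' @param sweep An `abeta_sweep` result (ordered or orderable by `value`).
#' @return Tibble with one row per transition: `lower`, `upper`,
#'   `from_regime`, `to_regime`. Empty when the regime never changes.
#' @export
classify_bifurcation <- function(sweep) {
  s <- dplyr::arrange(dplyr::filter(as_tibble(sweep), .data$ok), .data$value)
  if (nrow(s) < 2L)
    return(tibble(lower = numeric(), upper = numeric(),
                  from_regime = character(), to_regime = character()))
  chg <- which(s$regime[-1L] != s$regime[-nrow(s)])
  tibble(lower = s$value[chg], upper = s$value[chg + 1L],
         from_regime = s$regime[chg], to_regime = s$regime[chg + 1L])
}

#' Write a bifurcation table as CSV
#'
#' Columns: `param,value,period_s,norm_amplitude,regime`.
#' @param sweep An `abeta_sweep`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bifurcation_table <- function(sweep, path) {
  cols <- c("param", "value", "period_s", "norm_amplitude", "regime")
  utils::write.csv(as.data.frame(sweep)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Export contour-map slabs from a 3-parameter grid
#'
#' One delimited text file per (steep, k_infl) slab with rows = `infl_ref`
#' values and columns = time samples of the analyzed field, plus a JSON
#' sidecar describing all axes. Requires the grid to have been run with
#' `keep_traces = TRUE`.
#'
#' @param grid An `abeta_grid3` with traces.
#' @param dir Output directory (created if missing).
#' @param decimate Keep every `decimate`-th time sample (default 10).
#' @return Invisibly, the sidecar path.
#' @export
write_contour_slabs <- function(grid, dir, decimate = 10L) {
  if (!"trace" %in% names(grid))
    abort("grid was run without `keep_traces = TRUE`")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr1 <- grid$trace[[which(grid$ok)[1L]]]
  tsel <- seq(1L, nrow(tr1), by = decimate)
  slabs <- dplyr::group_split(dplyr::group_by(grid, .data$steep, .data$k_infl))
  files <- character()
  for (sl in slabs) {
    fn <- file.path(dir, sprintf("slab_steep%g_kinfl%g.csv",
                                 sl$steep[1L], sl$k_infl[1L]))
    mat <- t(vapply(sl$trace, function(tr) tr[[2L]][tsel],
                    numeric(length(tsel))))
    utils::write.table(cbind(infl_ref = sl$infl_ref, mat), fn, sep = ",",
                       row.names = FALSE,
                       col.names = c("infl_ref",
                                     sprintf("t%g", tr1$time[tsel])))
    files <- c(files, fn)
  }
  sidecar <- file.path(dir, "axes.json")
  jsonlite::write_json(
    list(time_s = tr1$time[tsel],
         steep = sort(unique(grid$steep)),
         k_infl = sort(unique(grid$k_infl)),
         infl_ref = sort(unique(grid$infl_ref)),
         files = basename(files)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' @export
autoplot.abeta_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("value", "period_s", "norm_amplitude")],
    -"value", names_to = "metric", values_to = "y")
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$y)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = unique(object$param), y = NULL)
}
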