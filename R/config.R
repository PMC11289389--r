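#' Load a run configuration file
#'
#' Reads a YAML (or JSON; YAML is a superset) configuration and merges it
#' over the preset defaults. Recognized top-level keys:
#' `preset` (closed / open_uncoupled / open_coupled), `overrides` (map of
#' flat parameter keys, see [param_keys()]), `m0_uM`, `t_end`, `sampling`
#' (log / uniform / window), `dt`, `window_start`, `field`,
#' `stabilization_s`, `sweep` (map with `param`, and either `values` or
#' `from`/`to`/`steps` plus optional `scale: log`), `output`, `verbosity`.
#' Unknown keys, unknown parameter names and invariant violations raise a
#' config error naming the offending key. An empty file yields the preset
#' defaults.
#'
#' @param path Path to the configuration file.
#' @param preset Preset used when the file does not name one
#'   (default `"open_coupled"`).
#' @return A list of class `run_config` with elements `preset`, `params`
#'   (fully resolved [abeta_parameters()]), `init`, and the simulation /
#'   sweep settings.
#' @export
load_config <- function(path, preset = "open_coupled") {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("preset", "overrides", "m0_uM", "t_end", "sampling", "dt",
             "window_start", "field", "stabilization_s", "sweep", "output",
             "verbosity")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  preset_name <- cfg$preset %||% preset
  ps <- abeta_preset(preset_name, m0_uM = cfg$m0_uM %||% 0)
  params <- apply_overrides(ps$params, cfg$overrides %||% list())
  sweep <- NULL
  if (!is.null(cfg$sweep)) {
    sw <- cfg$sweep
    if (is.null(sw$param)) abort("config key `sweep` needs a `param` entry")
    if (!sw$param %in% param_keys())
      abort(paste0("unknown sweep parameter `", sw$param, "`"))
    values <- if (!is.null(sw$values)) as.numeric(sw$values) else {
      if (is.null(sw$from) || is.null(sw$to) || is.null(sw$steps))
        abort("sweep needs `values` or `from`/`to`/`steps`")
      if (identical(sw$scale, "log"))
        10^seq(log10(sw$from), log10(sw$to), length.out = sw$steps)
      else seq(sw$from, sw$to, length.out = sw$steps)
    }
    sweep <- list(param = sw$param, values = values)
  }
  structure(list(
    preset = preset_name,
    params = params,
    init = ps$init,
    t_end = cfg$t_end %||% NULL,
    sampling = cfg$sampling %||% NULL,
    dt = cfg$dt %||% 1,
    window_start = cfg$window_start %||% 5e4,
    field = cfg$field %||% "a_m",
    stabilization_s = cfg$stabilization_s %||% 5e4,
    sweep = sweep,
    output = cfg$output %||% NULL,
    verbosity = cfg$verbosity %||% 1L
  ), class = "run_config")
}

#' Write the fully resolved configuration back to YAML
#'
#' Round-trips with [load_config()]: reloading the written file reproduces
#' the same resolved parameter set.
#'
#' @param config A `run_config` from [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  pars <- tidy(config$params)
  overrides <- as.list(setNames(pars$value, pars$parameter))
  out <- list(preset = config$preset, overrides = overrides)
  for (key in c("t_end", "sampling", "dt", "window_start", "field",
                "stabilization_s", "output", "verbosity"))
    if (!is.null(config[[key]])) out[[key]] <- config[[key]]
  if (!is.null(config$sweep))
    out$sweep <- list(param = config$sweep$param,
                      values = config$sweep$values)
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}
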