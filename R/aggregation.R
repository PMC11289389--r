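#' Logistic fit of a fibril growth curve
#'
#' Least-squares fit of the symmetric logistic
#' \eqn{f(t) = L / (1 + e^{-k (t - t_0)})} to a sigmoidal signal, typically
#' the fibril mass fraction of a closed-system run. The growth constant `k`
#' is the aggregation rate; the lag time is the t-axis intercept of the
#' tangent at the inflection point, \eqn{t_0 - 2/k}.
#'
#' When the samples are log-spaced in time, each residual is weighted by its
#' trapezoid width so the objective approximates a uniform-in-time
#' least-squares integral (the convention under dense uniform sampling),
#' independent of the sampling layout.
#'
#' @param data Data frame holding the trajectory (e.g. an `abeta_tc`).
#' @param signal Column with the sigmoidal signal (tidy-eval); for a closed
#'   run use the fibril mass fraction `a_f / total`.
#' @param time Column with sample times in seconds (default `time`).
#' @return An object of class `logistic_fit` with fields `plateau`,
#'   `growth_rate` (1/s), `midpoint_time` (s), `lag_time` (s),
#'   `residual_norm`, `n`. See [tidy.logistic_fit()].
#' @examples
#' tt <- seq(0, 4e4, by = 100)
#' d <- data.frame(time = tt, y = 1 / (1 + exp(-1e-3 * (tt - 1e4))))
#' fit <- fit_logistic(d, y)
#' tidy(fit)
#' @export
fit_logistic <- function(data, signal, time = time) {
  tt <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ signal }})
  ok <- is.finite(tt) & is.finite(y)
  tt <- tt[ok]; y <- y[ok]
  if (length(y) < 10L) abort("logistic fit needs at least 10 samples")
  plateau0 <- max(y)
  if (plateau0 <= 0 || diff(range(y)) <= 0)
    abort("logistic fit error: signal has no rise (constant or non-positive)")
  # uniform-time measure via trapezoid weights
  w <- (c(diff(tt), 0) + c(0, diff(tt))) / 2
  t_half <- tt[which.max(y >= plateau0 / 2)]
  slope0 <- max(diff(y) / diff(tt), na.rm = TRUE)
  k0 <- max(4 * slope0 / plateau0, 1e-8)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ L / (1 + exp(-k * (tt - t0))),
      start = list(L = plateau0, k = k0, t0 = t_half),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort(paste0("logistic fit did not converge: ",
                                     conditionMessage(e))))
  cf <- coef(fit)
  if (!is.finite(cf[["k"]]) || cf[["k"]] <= 0)
    abort(sprintf("logistic fit error: non-positive growth constant (k = %g)",
                  cf[["k"]]))
  structure(
    list(plateau = cf[["L"]], growth_rate = cf[["k"]],
         midpoint_time = cf[["t0"]],
         lag_time = cf[["t0"]] - 2 / cf[["k"]],
         residual_norm = sqrt(sum(w * stats::residuals(fit)^2) / sum(w)),
         n = length(y)),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(paste0("<logistic_fit> plateau = %.4g, growth_rate = %.4g /s, ",
                     "midpoint = %.4g s, lag = %.4g s\n"),
              x$plateau, x$growth_rate, x$midpoint_time, x$lag_time))
  invisible(x)
}

#' Tidiers for logistic fits
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per fitted quantity; `glance()`: one-row fit
#'   summary.
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(term = c("plateau", "growth_rate", "midpoint_time", "lag_time"),
         estimate = c(x$plateau, x$growth_rate, x$midpoint_time, x$lag_time))
}

#' @rdname tidy.logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(plateau = x$plateau, growth_rate = x$growth_rate,
         midpoint_time = x$midpoint_time, lag_time = x$lag_time,
         residual_norm = x$residual_norm, n = x$n)
}

#' Double-log scaling exponents of rate and lag time
#'
#' Ordinary least squares of `log10(growth_rate)` and `log10(lag_time)`
#' against `log10(conc)`, giving the apparent molecular orders of the
#' aggregation rate and the lag time with respect to initial monomer
#' concentration. The exponents are invariant under unit rescaling of
#' either axis (only intercepts shift).
#'
#' @param data Data frame with one row per initial concentration.
#' @param conc Column of initial monomer concentrations (any consistent unit).
#' @param rate Column of logistic growth constants (1/s).
#' @param lag Column of lag times (s); non-positive lags are dropped from the
#'   lag regression.
#' @return A tibble of class `scaling_fit`: one row per observable
#'   (`"rate"`, `"lag"`) with `exponent`, `intercept`, `r_squared`,
#'   `n_points`.
#' @examples
#' d <- data.frame(conc = c(0.1, 1, 10), rate = 2 * c(0.1, 1, 10)^1.5,
#'                 lag = 5 / c(0.1, 1, 10))
#' scaling_exponents(d)
#' @export
scaling_exponents <- function(data, conc = conc, rate = agg_rate_per_s,
                              lag = lag_time_s) {
  cc <- dplyr::pull(data, {{ conc }})
  rr <- dplyr::pull(data, {{ rate }})
  ll <- dplyr::pull(data, {{ lag }})
  fit1 <- function(x, y, label) {
    keep <- is.finite(x) & is.finite(y) & x > 0 & y > 0
    if (sum(keep) < 3L)
      abort(paste0("scaling fit for ", label,
                   " needs at least 3 positive points"))
    m <- lm(log10(y[keep]) ~ log10(x[keep]))
    # exact power laws are legitimate input; silence the perfect-fit note
    r2 <- suppressWarnings(summary(m)$r.squared)
    tibble(observable = label,
           exponent = unname(coef(m)[2L]),
           intercept = unname(coef(m)[1L]),
           r_squared = r2,
           n_points = sum(keep))
  }
  out <- dplyr::bind_rows(fit1(cc, rr, "rate"), fit1(cc, ll, "lag"))
  class(out) <- c("scaling_fit", class(out))
  out
}

#' Species population relative to total peptide mass
#'
#' Expresses one species of a closed-system trajectory as a percentage of the
#' initial monomer mass. For oligomers, the attached attribute `peak` also
#' reports the maximum fraction and the time span over which the fraction
#' stays above half its maximum.
#'
#' @param tc Trajectory (`abeta_tc` or data frame with `time` and the state
#'   columns).
#' @param species `"monomer"`, `"oligomer"` or `"fibril"`.
#' @param total Total peptide mass (initial monomer concentration, M; > 0).
#' @return Tibble with columns `time` and `pct`.
#' @export
relative_population <- function(tc, species = c("monomer", "oligomer", "fibril"),
                                total) {
  species <- match.arg(species)
  if (!is.numeric(total) || length(total) != 1L || !is.finite(total) || total <= 0)
    abort("`total` must be a single positive number")
  col <- switch(species, monomer = "a_m", oligomer = "a_o", fibril = "a_f")
  out <- tibble(time = tc$time, pct = 100 * tc[[col]] / total)
  if (species == "oligomer") {
    pk <- max(out$pct)
    above <- out$time[out$pct >= pk / 2]
    attr(out, "peak") <- list(
      max_pct = pk,
      time_at_max = out$time[which.max(out$pct)],
      half_max_span = if (length(above)) range(above) else c(NA_real_, NA_real_))
  }
  out
}

#' Average fibril length in monomers per fibril
#'
#' Ratio of fibril mass to fibril particle concentration. Undefined
#' (returned as `NA`) where no fibril particles exist yet, which is the
#' normal pre-nucleation situation rather than an error.
#'
#' @param a_f Fibril mass concentration (monomer equivalents, M); vectorized.
#' @param a_fp Fibril particle concentration (M); vectorized.
#' @return Numeric vector of average lengths (dimensionless).
#' @export
average_fibril_length <- function(a_f, a_fp) {
  if (any(a_fp < 0, na.rm = TRUE)) abort("`a_fp` must be non-negative")
  out <- ifelse(a_fp > 0, a_f / a_fp, NA_real_)
  as.numeric(out)
}

#' Closed-system aggregation scan over a concentration ladder
#'
#' Simulates the closed system at each initial monomer concentration, fits
#' the logistic to the fibril mass fraction, and collects the in vitro-style
#' observables per concentration.
#'
#' @param concentrations_uM Initial monomer concentrations in micromolar
#'   (default: the 13-value ladder, [abeta_ladder()]).
#' @param t_end Horizon in seconds (default 1e7).
#' @param n Log-spaced samples per run (default 800).
#' @param params Optional parameter override (defaults to the closed preset).
#' @return A tibble of class `abeta_scan`, one row per concentration:
#'   `m0_uM`, `agg_rate_per_s`, `lag_time_s`, `midpoint_s`, `plateau_frac`,
#'   `final_avg_length`, `peak_oligomer_pct`. The individual `logistic_fit`
#'   objects are attached as attribute `fits`.
#' @examples
#' \donttest{
#' scan <- aggregation_scan(c(0.1, 1, 10))
#' scaling_exponents(scan, conc = m0_uM)
#' }
#' @export
aggregation_scan <- function(concentrations_uM = abeta_ladder(),
                             t_end = 1e7, n = 800, params = NULL) {
  if (length(concentrations_uM) < 1L || any(concentrations_uM <= 0))
    abort("`concentrations_uM` must be positive")
  fits <- list()
  rows <- purrr::map(concentrations_uM, function(m0) {
    preset <- abeta_preset("closed", m0_uM = m0)
    if (!is.null(params)) preset$params <- params
    tc <- simulate_abeta(preset, t_end = t_end, sampling = "log", n = n)
    total <- m0 * 1e-6
    frac_df <- dplyr::mutate(as_tibble(tc), frac = .data$a_f / total)
    fit <- fit_logistic(frac_df, signal = frac)
    fits[[as.character(m0)]] <<- fit
    last <- dplyr::slice_tail(as_tibble(tc), n = 1)
    tibble(
      m0_uM = m0,
      agg_rate_per_s = fit$growth_rate,
      lag_time_s = fit$lag_time,
      midpoint_s = fit$midpoint_time,
      plateau_frac = fit$plateau,
      final_avg_length = average_fibril_length(last$a_f, last$a_fp),
      peak_oligomer_pct = max(100 * tc$a_o / total))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  class(out) <- c("abeta_scan", class(out))
  out
}

#' Write an aggregation scan as CSV
#'
#' Columns: `m0_uM,agg_rate_per_s,lag_time_s,final_avg_length,peak_oligomer_pct`.
#'
#' @param scan Result of [aggregation_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aggregation_scan <- function(scan, path) {
  cols <- c("m0_uM", "agg_rate_per_s", "lag_time_s", "final_avg_length",
            "peak_oligomer_pct")
  utils::write.csv(as.data.frame(scan)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @export
autoplot.abeta_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("m0_uM", "agg_rate_per_s", "lag_time_s")],
    -"m0_uM", names_to = "observable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$m0_uM, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = expression("initial monomer (" * mu * "M)"), y = NULL)
}
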