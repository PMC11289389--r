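#' Gaussian smoothing of a uniformly sampled series
#'
#' Convolution with a Gaussian kernel of width `sigma` (in samples), the
#' light blurring applied before peak detection. The default width follows
#' the maximum-sensitivity convention \eqn{\sigma = (\log_{10}(n)/2)^2}
#' (6.25 samples for n = 1e5). Edges are handled by renormalizing the
#' truncated kernel so the output has the same length as the input and a
#' constant series is preserved exactly. `sigma = 0` returns the input
#' unchanged.
#'
#' @param x Numeric series, uniformly sampled.
#' @param sigma Kernel standard deviation in samples; `NULL` for the default.
#' @return Smoothed numeric vector, same length as `x`.
#' @export
smooth_gaussian <- function(x, sigma = NULL) {
  n <- length(x)
  if (n < 10L) abort("series too short to smooth (n < 10)")
  if (is.null(sigma)) sigma <- default_sigma(n)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    abort("`sigma` must be a single non-negative number")
  if (sigma == 0) return(x)
  r <- max(1L, ceiling(4 * sigma))
  kern <- dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  xp <- c(rep(NA_real_, r), x, rep(NA_real_, r))
  out <- numeric(n)
  # renormalized kernel at the edges (missing neighbours get zero weight)
  for (i in seq_len(n)) {
    seg <- xp[i:(i + 2L * r)]
    w <- kern[!is.na(seg)]
    out[i] <- sum(seg[!is.na(seg)] * w) / sum(w)
  }
  out
}

#' Default smoothing width for peak detection
#' @param n Number of samples.
#' @return \eqn{(\log_{10}(n)/2)^2} in samples.
#' @export
default_sigma <- function(n) (log10(n) / 2)^2

#' Peaks and troughs of a series
#'
#' Local maxima of the (already smoothed) series; troughs are obtained as the
#' peaks of the negated series. All strict local extrema are reported
#' (maximum-sensitivity mode); empty results are valid, e.g. for monotone
#' series.
#'
#' @param signal Numeric series.
#' @param times Sample times (same length as `signal`).
#' @return List with tibbles `peaks` and `troughs` (columns `time`, `value`).
#' @export
find_extrema <- function(signal, times) {
  stopifnot(length(signal) == length(times))
  pick <- function(x) {
    pk <- pracma::findpeaks(x)
    if (is.null(pk)) return(tibble(time = numeric(), value = numeric()))
    ord <- order(pk[, 2L])
    tibble(time = times[pk[ord, 2L]], value = pk[ord, 1L])
  }
  peaks <- pick(signal)
  troughs <- pick(-signal)
  troughs$value <- -troughs$value
  list(peaks = peaks, troughs = troughs)
}

#' Summarize oscillations in a trajectory window
#'
#' Quantifies the steady oscillation (if any) of one state variable after a
#' stabilization cutoff: the series is Gaussian-smoothed, peaks and troughs
#' are located, and the period is the mean peak-to-peak spacing of the last
#' five peaks. The baseline is the midpoint between the mean of the last five
#' peak values and the mean of the last five trough values, and the
#' normalized amplitude is the mean peak-minus-trough excursion divided by
#' that baseline; a signal oscillating between 0 and any positive value
#' therefore attains the maximal normalized amplitude of 2.
#'
#' Regimes: `steady_oscillation` if at least five peaks were found, the last
#' five cycle amplitudes vary by less than 10% (relative), and the normalized
#' amplitude exceeds 0.01; `damped` if peaks exist but the oscillation fails
#' those checks (its period is still reported, but peak spacing of decaying
#' oscillations can be irregular); `monotonic` otherwise (period and
#' amplitude are `NA`).
#'
#' @param tc Trajectory (`abeta_tc` or data frame) sampled uniformly at least
#'   from `stabilization_s` onwards.
#' @param field State variable to analyze (default `"a_m"`, the clearest
#'   oscillation readout).
#' @param stabilization_s Cutoff before which the transient is discarded
#'   (default 5e4 s).
#' @param sigma Smoothing width in samples; `NULL` for [default_sigma()].
#' @return One-row tibble of class `oscillation_summary`: `period_s`,
#'   `norm_amplitude`, `baseline`, `n_peaks`, `regime`.
#' @examples
#' tt <- seq(5e4, 1.5e5)
#' tc <- data.frame(time = tt, a_m = 1 + 0.5 * sin(2 * pi * tt / 3000))
#' summarize_oscillation(tc)
#' @export
summarize_oscillation <- function(tc, field = "a_m", stabilization_s = 5e4,
                                  sigma = NULL) {
  if (!field %in% names(tc)) abort(paste0("no column `", field, "` in `tc`"))
  keep <- tc$time >= stabilization_s
  tt <- tc$time[keep]
  x <- tc[[field]][keep]
  if (length(x) < 10L)
    abort("too few samples after the stabilization cutoff")
  dts <- diff(tt)
  if (diff(range(dts)) > 1e-6 * stats::median(dts))
    abort("oscillation analysis requires uniform sampling after the cutoff")
  sm <- smooth_gaussian(x, sigma = sigma)
  ext <- find_extrema(sm, tt)
  pk <- ext$peaks; tr <- ext$troughs
  n_peaks <- nrow(pk)

  empty <- function(regime) {
    structure(tibble(period_s = NA_real_, norm_amplitude = NA_real_,
                     baseline = NA_real_, n_peaks = n_peaks, regime = regime),
              class = c("oscillation_summary", class(tibble())))
  }
  if (n_peaks < 2L || nrow(tr) < 1L) return(empty("monotonic"))

  l5p <- tail(pk, 5L)
  l5t <- tail(tr, 5L)
  period <- mean(diff(l5p$time))
  baseline <- (mean(l5p$value) + mean(l5t$value)) / 2
  amp <- if (baseline > 0) (mean(l5p$value) - mean(l5t$value)) / baseline else 0
  cyc <- l5p$value - mean(l5t$value)
  amp_var <- if (max(cyc) > 0) (max(cyc) - min(cyc)) / max(cyc) else Inf
  regime <- if (n_peaks >= 5L && is.finite(amp_var) && amp_var < 0.10 &&
                amp > 0.01) "steady_oscillation" else "damped"
  structure(tibble(period_s = period, norm_amplitude = amp,
                   baseline = baseline, n_peaks = n_peaks, regime = regime),
            class = c("oscillation_summary", class(tibble())))
}

#' One-call oscillation analysis of a parameter set
#'
#' Simulates the system with the uniform-window sampling plan and summarizes
#' the oscillation of `field` after the stabilization cutoff.
#'
#' @param params Parameters or preset (see [simulate_abeta()]).
#' @param t_end Horizon (default 1.5e5 s: 5e4 s stabilization + 1e5 s
#'   analysis window at 1 s sampling).
#' @inheritParams summarize_oscillation
#' @inheritParams simulate_abeta
#' @return As [summarize_oscillation()].
#' @export
oscillate_abeta <- function(params, init = NULL, t_end = 1.5e5,
                            field = "a_m", stabilization_s = 5e4, dt = 1,
                            sigma = NULL) {
  tc <- simulate_abeta(params, init = init, t_end = t_end,
                       sampling = "window", dt = dt,
                       window_start = stabilization_s)
  summarize_oscillation(tc, field = field, stabilization_s = stabilization_s,
                        sigma = sigma)
}
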