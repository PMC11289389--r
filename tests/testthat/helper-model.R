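# Shared fixtures for the model tests. Everything is generated in code.

closed_params <- function(...) {
  apply_overrides(abeta_preset("closed")$params, list(...))
}

# random physically plausible states spanning the magnitudes seen in runs
random_states <- function(n, seed = 42L) {
  set.seed(seed)
  tibble::tibble(
    a_m  = 10^stats::runif(n, -12, -6),
    a_o  = 10^stats::runif(n, -15, -8),
    a_fp = 10^stats::runif(n, -18, -11),
    a_f  = 10^stats::runif(n, -14, -7),
    infl = 10^stats::runif(n, -6, 1))
}

# independent term-by-term evaluation of the five derivatives, written as
# plain formula transcription (the oracle for abeta_rhs)
rhs_oracle <- function(s, p) {
  resp <- if (s[["infl"]] > 0)
    s[["infl"]]^p$steep / (p$infl_ref^p$steep + s[["infl"]]^p$steep) else 0
  kp <- rate_facets(p$k_plus); km <- rate_facets(p$k_minus)
  k_plus <- kp[1] + (kp[2] - kp[1]) * resp
  k_minus <- km[1] + (km[2] - km[1]) * resp
  j1 <- get_param(p, "j1"); jn1 <- get_param(p, "j_neg1")
  j2 <- get_param(p, "j2"); j3 <- get_param(p, "j3"); j4 <- get_param(p, "j4")
  am <- s[["a_m"]]; ao <- s[["a_o"]]; afp <- s[["a_fp"]]; af <- s[["a_f"]]
  c(a_m = k_plus - k_minus * am - j1 * am^p$n1 + jn1 * ao -
        p$nconv / (1 + p$nconv) * j2 * am^p$nconv * ao -
        j3 * am * afp - j4 * am^p$n2 * af,
    a_o = j1 * am^p$n1 - jn1 * ao -
        1 / (1 + p$nconv) * j2 * am^p$nconv * ao +
        j4 * am^p$n2 * af - p$gamma_o * k_minus * ao,
    a_fp = j2 * am^p$nconv * ao,
    a_f = j2 * am^p$nconv * ao + j3 * am * afp - p$gamma_f * k_minus * af,
    infl = p$delta_o * ao + p$delta_f * af - p$k_infl * s[["infl"]])
}

rate_facets <- function(x) {
  if (inherits(x, "coupled_rate")) c(x$c0, x$c_inf) else c(x, x)
}

# fixed-step classical RK4 over [0, t_end] built on the independent
# term-by-term oracle; reference integrator for short horizons
rk4_reference <- function(params, y0, t_end, dt) {
  f <- function(y) unname(rhs_oracle(stats::setNames(pmax(y, 0), state_names()),
                                     params))
  y <- unname(y0)
  for (i in seq_len(round(t_end / dt))) {
    k1 <- f(y); k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2); k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  stats::setNames(y, state_names())
}
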