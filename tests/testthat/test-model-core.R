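test_that("hill response has exact limits, half-maximum and steep saturation", {
  expect_identical(hill_response(0, 0.1, 50), 0)
  expect_equal(hill_response(0.1, 0.1, 50), 0.5)
  # doubling infl at steepness 50: 2^50 / (1 + 2^50), evaluated independently
  expect_equal(hill_response(0.2, 0.1, 50), 1 / (1 + 2^-50), tolerance = 1e-14)
  expect_error(hill_response(-0.1, 0.1, 50), "non-negative")
  expect_error(hill_response(NaN, 0.1, 50), "finite")
  expect_error(hill_response(0.1, 0, 50), "positive")
  expect_error(hill_response(0.1, 0.1, -2), "positive")
})

test_that("hill response is monotone and bounded on random triples", {
  set.seed(7)
  for (i in 1:200) {
    ref <- 10^stats::runif(1, -3, 0)
    st <- stats::runif(1, 0.5, 80)
    x <- sort(10^stats::runif(3, -6, 2))
    r <- hill_response(x, ref, st)
    expect_true(all(diff(r) >= 0))
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("effective rate interpolates between the inflammation limits", {
  cr <- coupled_rate(3.1e-7, 8.8e-6)
  expect_identical(effective_rate(cr, 0), 3.1e-7)
  expect_identical(effective_rate(cr, 1), 8.8e-6)
  # arithmetic midpoint of the fast-turnover clearance pair
  expect_equal(effective_rate(coupled_rate(2.78e-4, 1.39e-3), 0.5), 8.34e-4)
  r <- effective_rate(cr, seq(0, 1, 0.1))
  expect_true(all(r >= 3.1e-7 & r <= 8.8e-6))
  expect_error(effective_rate(cr, 1.2), "\\[0, 1\\]")
  expect_error(effective_rate(cr, -0.1), "\\[0, 1\\]")
})

test_that("derivatives vanish at the empty closed system and track pure generation", {
  p_closed <- abeta_preset("closed")$params
  zero <- stats::setNames(numeric(5), state_names())
  expect_identical(unname(abeta_rhs(zero, p_closed)), rep(0, 5))
  p_gen <- abeta_preset("open_uncoupled")$params
  d <- abeta_rhs(zero, p_gen)
  expect_identical(unname(d), c(1e-12, 0, 0, 0, 0))
})

test_that("derivatives match an independent term-by-term evaluation", {
  p <- abeta_preset("closed")$params
  s <- c(a_m = 1e-6, a_o = 1e-9, a_fp = 1e-12, a_f = 1e-8, infl = 0)
  expect_equal(abeta_rhs(s, p), rhs_oracle(s, p), tolerance = 1e-10)
  # and with active coupling at a nonzero inflammation level
  p2 <- abeta_preset("open_coupled")$params
  s2 <- c(a_m = 3e-8, a_o = 5e-10, a_fp = 2e-12, a_f = 4e-9, infl = 0.27)
  expect_equal(abeta_rhs(s2, p2), rhs_oracle(s2, p2), tolerance = 1e-10)
})

test_that("closed-system derivatives conserve total peptide mass", {
  p <- abeta_preset("closed")$params
  states <- random_states(1000)
  for (i in seq_len(nrow(states))) {
    d <- abeta_rhs(states[i, ], p)
    expect_lt(abs(d[["a_m"]] + d[["a_o"]] + d[["a_f"]]), 1e-25)
  }
})

test_that("fibril particle count never decreases", {
  for (preset in c("closed", "open_uncoupled", "open_coupled")) {
    p <- abeta_preset(preset)$params
    states <- random_states(200, seed = 11L)
    for (i in seq_len(nrow(states)))
      expect_gte(abeta_rhs(states[i, ], p)[["a_fp"]], 0)
  }
})

test_that("the coupled model reduces to the uncoupled one without inflammation", {
  p <- abeta_preset("open_coupled")$params
  p <- apply_overrides(p, list(delta_o = 0, delta_f = 0))
  # with infl = 0 all effective rates sit at their c0 values
  p_c0 <- apply_overrides(p, list(
    k_plus = get_param(p, "k_plus_0"), k_minus = get_param(p, "k_minus_0")))
  states <- random_states(50, seed = 3L)
  states$infl <- 0
  for (i in seq_len(nrow(states))) {
    d1 <- abeta_rhs(states[i, ], p)
    d2 <- abeta_rhs(states[i, ], p_c0)
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_identical(d1[["infl"]], 0)
  }
  # and infl stays identically zero along a trajectory
  tc <- simulate_abeta(p, init = c(a_m = 1e-7, a_o = 0, a_fp = 0, a_f = 0,
                                   infl = 0), t_end = 1e5, sampling = "log",
                       n = 100)
  expect_true(all(tc$infl == 0))
})

test_that("parameter construction enforces the invariants", {
  expect_error(abeta_parameters(n1 = -1), "n1")
  expect_error(abeta_parameters(gamma_o = -0.1), "non-negative")
  expect_error(abeta_parameters(j_neg2 = 1e-3), "irreversible")
  expect_error(coupled_rate(-1), "non-negative")
  expect_error(set_param(abeta_parameters(), "bogus", 1), "unknown parameter")
  p <- set_param(abeta_parameters(), "k_minus_inf", 5 * 2.78e-5)
  expect_equal(get_param(p, "k_minus_inf"), 1.39e-4)
  expect_equal(get_param(p, "k_minus_0"), 2.78e-5)
})

test_that("tidy() expands coupled rates into their facets", {
  td <- tidy(abeta_parameters())
  expect_true(all(c("k_plus_0", "k_plus_inf", "k_minus_0", "k_minus_inf",
                    "gamma_o", "steep") %in% td$parameter))
  expect_equal(td$value[td$parameter == "k_minus_inf"], 1.39e-4)
})
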