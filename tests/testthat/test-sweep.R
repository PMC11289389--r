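# sweeps run on a shortened window where only relative behavior matters, to
# keep the suite fast; acceptance checks use the full default window
sw_opts <- list(t_end = 9e4, stabilization_s = 5e4)

test_that("sweeping an inert parameter leaves every summary unchanged", {
  sw <- sweep_1d("gamma_f", c(0.01, 0.1, 1), base = mild_oscillation_params(),
                 t_end = sw_opts$t_end, stabilization_s = sw_opts$stabilization_s)
  expect_true(all(sw$ok))
  expect_equal(diff(range(sw$period_s)), 0, tolerance = 1e-6)
  expect_lt(diff(range(sw$norm_amplitude)), 1e-4)
  expect_length(unique(sw$regime), 1L)
})

test_that("fibrillation-rate sweeps do not alter the working-point oscillation", {
  base <- mild_oscillation_params()
  ref <- oscillate_abeta(base, t_end = sw_opts$t_end)
  for (spec in list(list("j2", c(1e7, 1e9, 1e11)),
                    list("j3", c(1e5, 1e6, 1e7)),
                    list("j4", c(2, 20, 200)))) {
    sw <- sweep_1d(spec[[1]], spec[[2]], base = base,
                   t_end = sw_opts$t_end,
                   stabilization_s = sw_opts$stabilization_s)
    expect_true(all(abs(sw$norm_amplitude - ref$norm_amplitude) < 0.1))
  }
})

test_that("sweep results are order-independent", {
  vals <- c(2e-3, 5e-4, 1e-3)
  base <- apply_overrides(abeta_preset("open_coupled")$params,
                          list(infl_ref = 0.005, steep = 50,
                               k_plus_0 = 7e-12, k_plus_inf = 0))
  sw1 <- sweep_1d("k_infl", vals, base = base, t_end = sw_opts$t_end,
                  stabilization_s = sw_opts$stabilization_s)
  sw2 <- sweep_1d("k_infl", sort(vals), base = base, t_end = sw_opts$t_end,
                  stabilization_s = sw_opts$stabilization_s)
  m1 <- dplyr::arrange(as.data.frame(sw1), value)
  m2 <- dplyr::arrange(as.data.frame(sw2), value)
  expect_equal(m1, m2)
})

test_that("the monomer-clearance sweep produces no steady oscillation", {
  sw <- sweep_1d("k_minus_0", c(1e-6, 1e-5, 1e-4, 5e-4),
                 base = mild_oscillation_params(),
                 linked = list(k_minus_inf = function(v) 5 * v),
                 t_end = 1.5e5)
  expect_true(all(sw$ok))
  expect_false(any(sw$regime == "steady_oscillation"))
})

test_that("a degenerate 1x1x1 grid equals a single run summary", {
  g <- sweep_grid3(k_infl = 0.003, steep = 50, infl_ref = 0.01,
                   t_end = sw_opts$t_end,
                   stabilization_s = sw_opts$stabilization_s)
  base <- apply_overrides(abeta_preset("open_coupled")$params,
                          list(k_infl = 0.003, steep = 50, infl_ref = 0.01))
  ref <- oscillate_abeta(base, t_end = sw_opts$t_end)
  expect_equal(g$period_s, ref$period_s)
  expect_equal(g$norm_amplitude, ref$norm_amplitude)
  expect_identical(g$regime, ref$regime)
})

test_that("grid cells agree with independent 1-D sweeps at matching coordinates", {
  g <- sweep_grid3(k_infl = c(1e-3, 3e-3), steep = 50, infl_ref = 0.005,
                   t_end = sw_opts$t_end,
                   stabilization_s = sw_opts$stabilization_s)
  base <- apply_overrides(abeta_preset("open_coupled")$params,
                          list(steep = 50, infl_ref = 0.005))
  sw <- sweep_1d("k_infl", c(1e-3, 3e-3), base = base, t_end = sw_opts$t_end,
                 stabilization_s = sw_opts$stabilization_s)
  g <- dplyr::arrange(g, .data$k_infl)
  expect_equal(g$period_s, sw$period_s)
  expect_equal(g$norm_amplitude, sw$norm_amplitude)
})

test_that("regime transitions are bracketed between adjacent grid points", {
  sw <- sweep_1d("gamma_o", c(0.05, 0.1, 0.3, 0.6),
                 base = mild_oscillation_params(), t_end = sw_opts$t_end,
                 stabilization_s = sw_opts$stabilization_s)
  bif <- classify_bifurcation(sw)
  expect_true(nrow(bif) >= 1L)
  expect_true(all(bif$lower < bif$upper))
  # damped ripples die out somewhere above gamma_o = 0.1
  expect_true(any(bif$to_regime == "monotonic"))
  flat <- sweep_1d("gamma_f", c(0.01, 0.1), base = mild_oscillation_params(),
                   t_end = sw_opts$t_end,
                   stabilization_s = sw_opts$stabilization_s)
  expect_equal(nrow(classify_bifurcation(flat)), 0L)
})

test_that("per-point failures are recorded, wholesale failure is fatal", {
  base <- mild_oscillation_params()
  sw <- sweep_1d("gamma_o", c(0.05, -1, 0.1), base = base,
                 t_end = sw_opts$t_end,
                 stabilization_s = sw_opts$stabilization_s)
  expect_identical(sw$ok, c(TRUE, FALSE, TRUE))
  expect_match(sw$message[2], "non-negative")
  expect_error(sweep_1d("gamma_o", c(-1, -2, 0.1), base = base,
                        t_end = sw_opts$t_end,
                        stabilization_s = sw_opts$stabilization_s),
               "failed at 2 of 3")
})

test_that("contour slabs export with a consistent JSON sidecar", {
  g <- sweep_grid3(k_infl = 0.003, steep = c(20, 50), infl_ref = c(0.005, 0.01),
                   t_end = 6e4, stabilization_s = 5e4, keep_traces = TRUE)
  dir <- withr::local_tempdir()
  write_contour_slabs(g, dir, decimate = 100L)
  ax <- jsonlite::read_json(file.path(dir, "axes.json"), simplifyVector = TRUE)
  expect_setequal(ax$steep, c(20, 50))
  expect_length(ax$files, 2L)
  slab <- utils::read.csv(file.path(dir, ax$files[1]), check.names = FALSE)
  expect_equal(nrow(slab), 2L)  # one row per infl_ref
  expect_equal(ncol(slab), 1L + length(ax$time_s))
})
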