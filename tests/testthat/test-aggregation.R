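test_that("exact logistic inputs are recovered to closed-form precision", {
  tt <- seq(0, 4e4, length.out = 600)
  d <- data.frame(time = tt, y = 1 / (1 + exp(-1e-3 * (tt - 1e4))))
  fit <- fit_logistic(d, y)
  expect_equal(fit$growth_rate, 1e-3, tolerance = 1e-6)
  expect_equal(fit$midpoint_time, 1e4, tolerance = 1e-6)
  # lag = t-axis intercept of the inflection tangent, t0 - 2/k
  expect_equal(fit$lag_time, 8000, tolerance = 1e-6)
  expect_equal(fit$plateau, 1, tolerance = 1e-6)
})

test_that("logistic recovery holds across the rate/midpoint grid", {
  for (k in c(1e-5, 1e-3, 1e-1)) {
    for (t0 in c(1e2, 1e4, 1e6)) {
      if (t0 < 4 / k) next  # curve must actually rise within positive time
      # coarse background grid plus samples resolving the transition,
      # mirroring log-spaced sampling of real runs
      tt <- sort(unique(c(seq(0, t0 + 10 / k, length.out = 300),
                          t0 + seq(-15, 15, length.out = 200) / k)))
      d <- data.frame(time = tt, y = 2.5 / (1 + exp(-k * (tt - t0))))
      fit <- fit_logistic(d, y)
      expect_equal(fit$growth_rate, k, tolerance = 1e-6)
      expect_equal(fit$midpoint_time, t0, tolerance = 1e-6)
    }
  }
})

test_that("degenerate signals raise fit errors", {
  d <- data.frame(time = seq(0, 100, 1), y = 0)
  expect_error(fit_logistic(d, y), "no rise")
  expect_error(fit_logistic(data.frame(time = 1:5, y = 1:5), y),
               "at least 10 samples")
})

test_that("tidiers expose the fitted quantities", {
  tt <- seq(0, 4e4, length.out = 200)
  fit <- fit_logistic(data.frame(time = tt,
                                 y = 1 / (1 + exp(-1e-3 * (tt - 1e4)))), y)
  td <- tidy(fit)
  expect_setequal(td$term, c("plateau", "growth_rate", "midpoint_time",
                             "lag_time"))
  gl <- glance(fit)
  expect_equal(gl$n, 200L)
  expect_lt(gl$residual_norm, 1e-8)
})

test_that("scaling exponents reproduce exact power laws and ignore units", {
  cc <- c(0.1, 1, 10)
  d <- data.frame(conc = cc, rate = 2 * cc^1.5, lag = 5 / cc)
  sf <- scaling_exponents(d, conc = conc, rate = rate, lag = lag)
  expect_equal(sf$exponent[sf$observable == "rate"], 1.5, tolerance = 1e-10)
  expect_equal(sf$exponent[sf$observable == "lag"], -1, tolerance = 1e-10)
  # rescaling the rate unit shifts the intercept, not the exponent
  d2 <- transform(d, rate = rate * 3600)
  sf2 <- scaling_exponents(d2, conc = conc, rate = rate, lag = lag)
  expect_equal(sf2$exponent, sf$exponent, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(sf2$intercept[1], sf$intercept[1])))
  expect_error(scaling_exponents(d[1:2, ], conc = conc, rate = rate,
                                 lag = lag), "at least 3")
})

test_that("relative populations start from pure monomer and flag the oligomer peak", {
  tc <- simulate_abeta(abeta_preset("closed", m0_uM = 1), t_end = 1e6,
                       sampling = "log", n = 200)
  mono <- relative_population(tc, "monomer", total = 1e-6)
  expect_equal(mono$pct[1], 100)
  olig <- relative_population(tc, "oligomer", total = 1e-6)
  expect_equal(olig$pct[1], 0)
  pk <- attr(olig, "peak")
  expect_equal(pk$max_pct, max(olig$pct))
  expect_true(pk$half_max_span[1] <= pk$time_at_max &&
                pk$time_at_max <= pk$half_max_span[2])
  expect_error(relative_population(tc, "oligomer", total = 0), "positive")
})

test_that("average fibril length is the mass/particle ratio, undefined pre-nucleation", {
  expect_equal(average_fibril_length(2e-9, 2e-9), 1)
  expect_equal(average_fibril_length(1e-6, 2e-11), 5e4)
  expect_true(is.na(average_fibril_length(0, 0)))
  expect_equal(average_fibril_length(c(1e-9, 0), c(1e-12, 0)),
               c(1000, NA_real_))
})

test_that("average fibril length never decreases along a closed run", {
  tc <- simulate_abeta(abeta_preset("closed", m0_uM = 1), t_end = 1e7,
                       sampling = "log", n = 300)
  len <- average_fibril_length(tc$a_f, tc$a_fp)
  len <- len[!is.na(len)]
  expect_true(all(diff(len) > -1e-9 * len[-1]))
})

test_that("the aggregation scan collects per-concentration observables", {
  scan <- aggregation_scan(c(0.1, 1, 10), n = 400)
  expect_s3_class(scan, "abeta_scan")
  expect_equal(scan$m0_uM, c(0.1, 1, 10))
  expect_true(all(scan$agg_rate_per_s > 0))
  expect_true(all(diff(scan$agg_rate_per_s) > 0))  # faster at higher conc
  expect_true(all(diff(scan$lag_time_s) < 0))      # shorter lag at higher conc
  expect_length(attr(scan, "fits"), 3L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_aggregation_scan(scan, path)
  expect_identical(
    names(utils::read.csv(path)),
    c("m0_uM", "agg_rate_per_s", "lag_time_s", "final_avg_length",
      "peak_oligomer_pct"))
})
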