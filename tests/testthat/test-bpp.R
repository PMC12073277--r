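test_that("bpp_rate obeys its motional limits", {
  omega0 <- 2 * pi * 25e6
  cc <- 5.7e7
  # extreme narrowing: rate -> 5 C tau
  tau <- 1e-3 / omega0
  expect_equal(bpp_rate(tau, omega0, cc), 5 * cc * tau, tolerance = 1e-3)
  # slow motion: rate -> 2 C / (omega0^2 tau)
  tau <- 1e3 / omega0
  expect_equal(bpp_rate(tau, omega0, cc), 2 * cc / (omega0^2 * tau),
               tolerance = 1e-3)
  expect_equal(bpp_rate(Inf, omega0, cc), 0)
})

test_that("arrhenius_tau evaluates, decreases with T and guards overflow", {
  expect_equal(arrhenius_tau(160.5, 2.4e-11, 6.8), 3.92e-9, tolerance = 1e-3)
  expect_equal(arrhenius_tau(200, 5e-12, 0), 5e-12)
  taus <- arrhenius_tau(seq(100, 300, 20), 1e-12, 10)
  expect_true(all(diff(taus) < 0))
  expect_identical(arrhenius_tau(0.1, 1e-12, 50), Inf)
})

test_that("t1_model adds rates across processes", {
  omega0 <- 2 * pi * 25e6
  p1 <- relaxation_process(5.7e7, 2.4e-11, 6.8)
  p2 <- relaxation_process(8e7, 5e-11, 12.9)
  both <- dplyr::bind_rows(p1, p2)
  t <- c(150, 200, 250)
  expect_equal(1 / t1_model(t, both, omega0),
               1 / t1_model(t, p1, omega0) + 1 / t1_model(t, p2, omega0))
  expect_true(all(t1_model(t, both, omega0) <=
                    pmin(t1_model(t, p1, omega0), t1_model(t, p2, omega0))))
})

test_that("the closed-form T1 minimum agrees with a dense scan", {
  proc <- relaxation_process(5.7e7, 2.4e-11, 6.8, "intermediate")
  m <- t1_minimum(proc, 25e6)
  tgrid <- seq(50, 400, by = 0.01)
  scan <- t1_model(tgrid, proc, 2 * pi * 25e6)
  expect_equal(m$t_min_K, tgrid[which.min(scan)], tolerance = 0.1)
  expect_equal(m$t1_min_s, min(scan), tolerance = 1e-6)
})

test_that("omega0*tau at the minimum is a universal constant of the spectral density", {
  vals <- withr::with_seed(21, {
    vapply(1:8, function(i) {
      proc <- relaxation_process(10^runif(1, 6, 9), 10^runif(1, -13, -10),
                                 runif(1, 2, 30))
      t1_minimum(proc, 10^runif(1, 6, 8))$omega_tau
    }, numeric(1))
  })
  expect_equal(vals, rep(0.6158, 8), tolerance = 1e-3)
})

test_that("T1 at the minimum scales as 1/C and the minimum shifts with frequency", {
  p <- relaxation_process(5.7e7, 2.4e-11, 6.8)
  p2 <- relaxation_process(2 * 5.7e7, 2.4e-11, 6.8)
  m1 <- t1_minimum(p, 25e6)
  m2 <- t1_minimum(p2, 25e6)
  expect_equal(m2$t1_min_s, m1$t1_min_s / 2, tolerance = 1e-9)
  expect_equal(m2$t_min_K, m1$t_min_K)

  m50 <- t1_minimum(p, 50e6)
  # higher frequency -> smaller tau* -> higher minimum temperature
  expect_gt(m50$t_min_K, m1$t_min_K)
  tau25 <- arrhenius_tau(m1$t_min_K, 2.4e-11, 6.8)
  tau50 <- arrhenius_tau(m50$t_min_K, 2.4e-11, 6.8)
  expect_equal(2 * pi * 25e6 * tau25, 2 * pi * 50e6 * tau50, tolerance = 1e-6)
})

test_that("two-process refits from perturbed starts recover the truth", {
  truth <- dplyr::bind_rows(
    relaxation_process(5.7e7, 2.4e-11, 6.8, "intermediate"),
    relaxation_process(8e7, 5e-11, 12.9, "high-temperature")
  )
  series <- gen_t1_curve(t1_curve_spec(truth, 25e6, seq(120, 300, 2)))
  init <- truth
  init$c_constant <- init$c_constant * c(1.6, 0.7)
  init$tau0 <- init$tau0 * c(0.5, 1.8)
  init$ea <- init$ea * c(1.25, 0.85)
  fit <- fit_t1_series(series, n_processes = 2, init = init)
  expect_equal(fit$processes$ea, c(6.8, 12.9), tolerance = 1e-2)
  expect_equal(fit$processes$tau0, c(2.4e-11, 5e-11), tolerance = 1e-2)
  expect_equal(fit$processes$c_constant, c(5.7e7, 8e7), tolerance = 1e-2)
  expect_lt(fit$residual_log_rms, 1e-6)
})

test_that("slope-only fitting recovers the activation energy of a narrowing branch", {
  proc <- relaxation_process(1e8, 1e-13, 9.5)
  series <- gen_t1_curve(t1_curve_spec(proc, 25e6, seq(220, 300, 4)))
  fit <- fit_t1_series(series, n_processes = 1, modes = "slope")
  expect_equal(fit$processes$ea, 9.5, tolerance = 1e-3)
  expect_true(is.na(fit$processes$c_constant))
})

test_that("activation energy survives 5% measurement noise (property)", {
  proc <- relaxation_process(5.7e7, 2.4e-11, 6.8, "intermediate")
  errs <- vapply(1:20, function(i) {
    series <- gen_t1_curve(t1_curve_spec(proc, 25e6, seq(110, 230, 4),
                                         noise_relative_sd = 0.05, seed = i))
    fit <- fit_t1_series(series, n_processes = 1, init = proc)
    abs(fit$processes$ea - 6.8) / 6.8
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("under-determined fits are rejected with a diagnostic", {
  proc <- relaxation_process(5.7e7, 2.4e-11, 6.8)
  series <- gen_t1_curve(t1_curve_spec(proc, 25e6, seq(150, 200, 10)))
  expect_error(fit_t1_series(series, n_processes = 2,
                             init = dplyr::bind_rows(proc, proc)),
               "under-determined", class = "asdkit_invalid")
})
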