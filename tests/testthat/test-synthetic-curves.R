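test_that("recovery generator matches its closed form and saturates at m0", {
  spec <- recovery_spec(data.frame(t1 = 0.35, fraction = 1), m0 = 2,
                        delays = c(0.35, 5, 500))
  curve <- gen_recovery(spec)
  expect_equal(curve$amplitude[1], 2 * (1 - exp(-1)))
  expect_equal(curve$amplitude[3], 2, tolerance = 1e-6)
})

test_that("recovery generator is seed-deterministic and validates input", {
  comp <- data.frame(t1 = 0.35, fraction = 1)
  a <- gen_recovery(recovery_spec(comp, noise_sd = 0.01, seed = 4))
  b <- gen_recovery(recovery_spec(comp, noise_sd = 0.01, seed = 4))
  c <- gen_recovery(recovery_spec(comp, noise_sd = 0.01, seed = 5))
  expect_identical(a$amplitude, b$amplitude)
  expect_false(identical(a$amplitude, c$amplitude))
  expect_error(recovery_spec(data.frame(t1 = -1, fraction = 1)), class = "asdkit_invalid")
  expect_error(recovery_spec(data.frame(t1 = c(1, 2, 3), fraction = rep(1 / 3, 3))),
               class = "asdkit_invalid")
  expect_error(recovery_spec(comp, delays = c(2, 1)), class = "asdkit_invalid")
})

test_that("FID generator normalises at the origin and obeys the Gaussian form", {
  spec <- fid_spec(m0 = 3, gaussian_fraction = 1, t2_gauss = 10, t2_exp = 80,
                   times = c(0, 10))
  curve <- gen_fid(spec)
  expect_equal(curve$amplitude[1], 3)
  expect_equal(curve$amplitude[2], 3 * exp(-0.5))
  expect_error(fid_spec(t2_gauss = 50, t2_exp = 10), class = "asdkit_invalid")
  expect_error(fid_spec(gaussian_fraction = 1.4), class = "asdkit_invalid")
})

test_that("T1(T) curves are hysteresis-free and reach the narrowing limit", {
  proc <- relaxation_process(5.7e7, 2.4e-11, 6.8)
  up <- gen_t1_curve(t1_curve_spec(proc, 25e6, seq(100, 300, 10)))
  down <- gen_t1_curve(t1_curve_spec(proc, 25e6, seq(300, 100, -10)))
  expect_equal(up$t1_s, rev(down$t1_s))
  # extreme narrowing: at low frequency omega*tau << 1 so T1 ~ 1/(5 C tau)
  lowfreq <- gen_t1_curve(t1_curve_spec(proc, 1e3, 250))
  tau <- arrhenius_tau(250, 2.4e-11, 6.8)
  expect_equal(lowfreq$t1_s, 1 / (5 * 5.7e7 * tau), tolerance = 1e-6)
})

test_that("T1 minimum of the generated curve sits where dense evaluation says", {
  proc <- relaxation_process(5.7e7, 2.4e-11, 6.8, "intermediate")
  tgrid <- seq(100, 300, by = 0.01)
  curve <- gen_t1_curve(t1_curve_spec(proc, 25e6, tgrid))
  t_at_min <- tgrid[which.min(curve$t1_s)]
  expect_equal(t_at_min, 160.5, tolerance = 0.01)
})

test_that("peak generator inverts Scherrer exactly and vanishes for large crystals", {
  spec <- peak_set_spec(data.frame(two_theta = 16.4, crystallite_size = 40.1))
  pk <- gen_peaks(spec)
  expect_equal(pk$fwhm, 0.200, tolerance = 5e-3)
  big <- gen_peaks(peak_set_spec(data.frame(two_theta = 16.4, crystallite_size = 1e9)))
  expect_lt(big$fwhm, 1e-6)
  expect_error(peak_set_spec(data.frame(two_theta = 200, crystallite_size = 10)),
               class = "asdkit_invalid")
})

test_that("achievable_counts rounds plans to integers with even bond ends", {
  cnt <- achievable_counts(c(0.184, 0.409, 0.287, 0.120), 120, pairwise = TRUE)
  expect_equal(sum(cnt), 120)
  expect_equal(sum(cnt * (seq_along(cnt) - 1)) %% 2, 0)
  # largest-remainder: close to the requested proportions
  expect_true(all(abs(cnt - c(0.184, 0.409, 0.287, 0.120) * 120) <= 1.5))
})
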