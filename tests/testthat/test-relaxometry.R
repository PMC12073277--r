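test_that("mono- and bi-exponential recovery parameters are recovered from noiseless data", {
  mono <- gen_recovery(recovery_spec(data.frame(t1 = 0.35, fraction = 1)))
  f1 <- fit_recovery(mono, 1)
  expect_equal(f1$t1, 0.35, tolerance = 1e-3)

  bi <- gen_recovery(recovery_spec(data.frame(t1 = c(0.36, 1.1),
                                              fraction = c(0.65, 0.35))))
  f2 <- fit_recovery(bi, 2)
  expect_equal(f2$t1, c(0.36, 1.1), tolerance = 5e-3)
  expect_equal(f2$fractions, c(0.65, 0.35), tolerance = 5e-3)
  expect_equal(sum(f2$fractions), 1, tolerance = 1e-9)
  expect_lt(f2$t1[1], f2$t1[2])
})

test_that("fits are invariant to amplitude rescaling", {
  bi <- gen_recovery(recovery_spec(data.frame(t1 = c(0.2, 0.9),
                                              fraction = c(0.5, 0.5)),
                                   noise_sd = 0.002, seed = 8))
  f_a <- fit_recovery(bi, 2)
  scaled <- dplyr::mutate(bi, amplitude = amplitude * 137)
  f_b <- fit_recovery(scaled, 2)
  expect_equal(f_a$t1, f_b$t1, tolerance = 1e-6)
  expect_equal(f_a$fractions, f_b$fractions, tolerance = 1e-6)
  expect_equal(f_b$m0, f_a$m0 * 137, tolerance = 1e-6)

  fid <- gen_fid(fid_spec(noise_sd = 0.002, seed = 8))
  d_a <- decompose_fid(fid)
  d_b <- decompose_fid(dplyr::mutate(fid, amplitude = amplitude * 42))
  expect_equal(d_a$t2_gauss, d_b$t2_gauss, tolerance = 1e-6)
  expect_equal(d_a$gaussian_fraction, d_b$gaussian_fraction, tolerance = 1e-6)
})

test_that("model selection prefers the correct exponentiality", {
  mono <- gen_recovery(recovery_spec(data.frame(t1 = 0.35, fraction = 1),
                                     noise_sd = 0.01, seed = 3))
  expect_identical(attr(select_recovery_model(mono), "selected"), "mono")

  bi <- gen_recovery(recovery_spec(data.frame(t1 = c(0.36, 1.1),
                                              fraction = c(0.65, 0.35)),
                                   noise_sd = 0.01, seed = 3))
  expect_identical(attr(select_recovery_model(bi), "selected"), "bi")

  # a 99/1 mixture is mono for practical purposes: the fraction floor rule
  skewed <- gen_recovery(recovery_spec(data.frame(t1 = c(0.3, 1.2),
                                                  fraction = c(0.99, 0.01)),
                                       noise_sd = 0.005, seed = 3))
  expect_identical(attr(select_recovery_model(skewed), "selected"), "mono")
})

test_that("FID decomposition recovers rigid and mobile parameters", {
  fid <- gen_fid(fid_spec(gaussian_fraction = 0.9, t2_gauss = 10, t2_exp = 80))
  fit <- decompose_fid(fid)
  expect_equal(fit$t2_gauss, 10, tolerance = 5e-3)
  expect_equal(fit$t2_exp, 80, tolerance = 5e-3)
  expect_equal(fit$gaussian_fraction, 0.9, tolerance = 5e-3)

  # plasticised state: longer mobile T2, 25% mobile fraction
  wet <- gen_fid(fid_spec(gaussian_fraction = 0.75, t2_gauss = 10, t2_exp = 200,
                          times = seq(0, 800, by = 0.5)))
  fw <- decompose_fid(wet)
  expect_equal(1 - fw$gaussian_fraction, 0.25, tolerance = 5e-3)
  expect_equal(fw$t2_exp, 200, tolerance = 5e-3)

  pure <- gen_fid(fid_spec(gaussian_fraction = 1, t2_gauss = 10, t2_exp = 80))
  fp <- decompose_fid(pure)
  expect_lte(1 - fp$gaussian_fraction, 0.01)
})

test_that("parameter recovery stays accurate under 1% noise (property)", {
  errs <- withr::with_seed(99, {
    vapply(1:60, function(i) {
      t1_true <- runif(1, 0.05, 5)
      curve <- gen_recovery(recovery_spec(
        data.frame(t1 = t1_true, fraction = 1),
        noise_sd = 0.01, seed = sample.int(1e6, 1)
      ))
      fit <- fit_recovery(curve, 1)
      abs(fit$t1 - t1_true) / t1_true
    }, numeric(1))
  })
  expect_lt(median(errs), 0.02)
})

test_that("noiseless fits match generating parameters to 0.5% (property)", {
  withr::with_seed(7, {
    for (i in 1:10) {
      t1s <- sort(runif(2, 0.05, 3) * c(1, 4))
      fr <- runif(1, 0.25, 0.75)
      curve <- gen_recovery(recovery_spec(data.frame(t1 = t1s,
                                                     fraction = c(fr, 1 - fr))))
      fit <- fit_recovery(curve, 2)
      expect_equal(fit$t1, t1s, tolerance = 5e-3)
      expect_equal(fit$fractions, c(fr, 1 - fr), tolerance = 5e-3)
    }
  })
})

test_that("proton fractions follow mole arithmetic", {
  half <- proton_fraction(data.frame(
    label = c("RSV", "PVP"), formula = c("C14H12O3", "C6H9NO"),
    weight_fraction = c(0.5, 0.5)
  ))
  expect_equal(half$proton_fraction[half$label == "RSV"], 0.394, tolerance = 1e-3)
  thirty <- proton_fraction(data.frame(
    label = c("RSV", "PVP"), formula = c("C14H12O3", "C6H9NO"),
    weight_fraction = c(0.3, 0.7)
  ))
  expect_equal(thirty$proton_fraction[thirty$label == "RSV"], 0.2177, tolerance = 1e-3)
  single <- proton_fraction(data.frame(formula = "C14H12O3", weight_fraction = 1))
  expect_equal(single$proton_fraction, 1)
  expect_error(
    proton_fraction(data.frame(formula = c("CO2", "O2"),
                               weight_fraction = c(0.5, 0.5))),
    class = "asdkit_invalid"
  )
})

test_that("phase assignment matches observed to predicted fractions", {
  bi <- gen_recovery(recovery_spec(data.frame(t1 = c(0.36, 1.1),
                                              fraction = c(0.65, 0.35))))
  fit <- fit_recovery(bi, 2)
  asg <- assign_phases(fit, data.frame(phase = c("PVP-rich", "RSV"),
                                       proton_fraction = c(0.63, 0.37)))
  expect_identical(asg$phase[asg$component == "long"], "RSV")
  expect_false(attr(asg, "ambiguous"))

  # humid-storage fractions: 0.74/0.26 observed against 0.63/0.37 predicted
  wet <- gen_recovery(recovery_spec(data.frame(t1 = c(0.17, 0.6),
                                               fraction = c(0.74, 0.26))))
  fw <- fit_recovery(wet, 2)
  asg2 <- assign_phases(fw, data.frame(phase = c("PVP-rich", "RSV"),
                                       proton_fraction = c(0.63, 0.37)))
  expect_identical(asg2$phase[asg2$component == "short"], "PVP-rich")
  expect_equal(asg2$mismatch, c(0.11, 0.11), tolerance = 5e-3)

  even <- fit_recovery(gen_recovery(recovery_spec(
    data.frame(t1 = c(0.2, 1.0), fraction = c(0.5, 0.5))
  )), 2)
  asg3 <- assign_phases(even, data.frame(phase = c("A", "B"),
                                         proton_fraction = c(0.5, 0.5)))
  expect_true(attr(asg3, "ambiguous"))
  expect_identical(asg3$phase, c("A", "B"))  # deterministic tie-break
})

test_that("stability reports flag steps and stay quiet for constants", {
  mono_fit <- function(t1, seed) {
    fit_recovery(gen_recovery(recovery_spec(
      data.frame(t1 = t1, fraction = 1), noise_sd = 1e-4, seed = seed
    )), 1)
  }
  stable <- lapply(1:10, function(i) mono_fit(0.35, i))
  rep1 <- stability_report(stable)
  expect_true(attr(rep1, "stable"))

  stepped <- lapply(1:6, function(i) mono_fit(if (i >= 2) 0.15 else 0.35, i))
  rep2 <- stability_report(stepped)
  expect_false(attr(rep2, "stable"))
  first <- attr(rep2, "first_change")
  expect_equal(min(first$time[startsWith(first$parameter, "t1")]), 2)

  dup <- stability_report(list(stable[[1]], stable[[1]]))
  expect_true(all(dup$relative_change == 0))

  fidf <- decompose_fid(gen_fid(fid_spec()))
  expect_error(stability_report(list(stable[[1]], fidf)), class = "asdkit_invalid")
})

test_that("tidy and glance expose fit results as tibbles", {
  fit <- fit_recovery(gen_recovery(recovery_spec(
    data.frame(t1 = c(0.36, 1.1), fraction = c(0.65, 0.35))
  )), 2)
  td <- tidy(fit)
  expect_identical(td$component, c("short", "long"))
  expect_equal(glance(fit)$n_components, 2L)

  fidfit <- decompose_fid(gen_fid(fid_spec()))
  expect_identical(tidy(fidfit)$component, c("gaussian", "exponential"))
  expect_true(is.numeric(glance(fidfit)$residual_rms))
})
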