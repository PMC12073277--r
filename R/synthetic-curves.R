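# Synthetic generators for relaxometry observables.
#
# Every generator produces the observable the instrument would, from known
# ground-truth parameters, so the downstream fitting stages can be tested by
# parameter recovery. The generating spec is attached to the output as the
# "ground_truth" attribute. Identical spec + seed gives a bit-identical curve.

#' Specification of a synthetic saturation-recovery curve
#'
#' Describes a mono- or bi-exponential magnetization recovery
#' \deqn{M(\tau) = M_0 \sum_i f_i (1 - e^{-\tau/T_{1,i}})}
#' plus optional additive Gaussian noise. The additive noise model reflects
#' baseline-subtracted amplitude data.
#'
#' @param components Data frame with columns `t1` (seconds, > 0) and
#'   `fraction` (> 0, summing to 1); one or two rows.
#' @param m0 Equilibrium amplitude (arbitrary units, > 0).
#' @param delays Recovery delays in seconds, strictly increasing, > 0.
#'   Defaults to the standard 64-point logarithmic grid from 5 ms to 50 s.
#' @param noise_sd Standard deviation of additive Gaussian amplitude noise
#'   (same units as `m0`; 0 for a noiseless curve).
#' @param seed Integer RNG seed used when `noise_sd > 0`.
#' @return A validated `recovery_spec` object.
#' @examples
#' recovery_spec(data.frame(t1 = 0.35, fraction = 1))
#' @export
recovery_spec <- function(components, m0 = 1,
                          delays = delay_grid(), noise_sd = 0, seed = 1L) {
  if (!is.data.frame(components) ||
      !all(c("t1", "fraction") %in% names(components))) {
    stop_invalid("`components` needs columns `t1` and `fraction`")
  }
  n <- nrow(components)
  if (n < 1L || n > 2L) stop_invalid("1 or 2 recovery components are supported")
  check_positive_vector(components$t1, "t1")
  check_fractions(components$fraction, "fraction")
  check_number(m0, "m0", lower = 0, strict_lower = TRUE)
  check_positive_vector(delays, "delays")
  check_increasing(delays, "delays")
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(components = as_tibble(components[c("t1", "fraction")]),
         m0 = m0, delays = as.numeric(delays),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "recovery_spec"
  )
}

#' Logarithmic saturation-recovery delay grid
#'
#' The standard acquisition grid: `n` delays log-spaced between `from` and
#' `to` seconds (default 64 points, 5 ms to 50 s).
#'
#' @param n Number of delays.
#' @param from,to First and last delay (seconds).
#' @return Numeric vector of delays in seconds.
#' @export
delay_grid <- function(n = 64, from = 5e-3, to = 50) {
  check_number(n, "n", lower = 2)
  check_number(from, "from", lower = 0, strict_lower = TRUE)
  check_number(to, "to", lower = from, strict_lower = TRUE)
  exp(seq(log(from), log(to), length.out = n))
}

#' Generate a synthetic saturation-recovery curve
#'
#' @param spec A [recovery_spec()].
#' @return A tibble with columns `delay_s` and `amplitude`, carrying the
#'   generating spec in the `ground_truth` attribute.
#' @examples
#' curve <- gen_recovery(recovery_spec(data.frame(t1 = 0.35, fraction = 1)))
#' head(curve)
#' @export
gen_recovery <- function(spec) {
  stopifnot(inherits(spec, "recovery_spec"))
  amp <- recovery_model(spec$delays, spec$m0,
                        spec$components$t1, spec$components$fraction)
  if (spec$noise_sd > 0) {
    amp <- amp + with_seed_(spec$seed, rnorm(length(amp), 0, spec$noise_sd))
  }
  out <- tibble(delay_s = spec$delays, amplitude = amp)
  attr(out, "ground_truth") <- spec
  out
}

# Mean recovery amplitude; shared by generator and fitter so the two stay
# one convention.
recovery_model <- function(tau, m0, t1, fraction) {
  drop(vapply(seq_along(t1),
              function(i) fraction[i] * (1 - exp(-tau / t1[i])),
              numeric(length(tau))) %*% rep(1, length(t1))) * m0
}

#' Specification of a synthetic free-induction decay
#'
#' Describes an FID as a rigid Gaussian plus mobile exponential component
#' \deqn{S(t) = M_0 [f_G e^{-t^2/(2 T_{2G}^2)} + (1-f_G) e^{-t/T_{2E}}]}
#' with optional additive Gaussian noise. Note the Gaussian convention
#' \eqn{e^{-t^2/2T_2^2}}: the alternative \eqn{e^{-(t/T_2)^2}} rescales
#' \eqn{T_{2G}} by \eqn{\sqrt 2}, so the convention is fixed package-wide.
#'
#' @param m0 Amplitude at `t = 0` (> 0).
#' @param gaussian_fraction Rigid (Gaussian) amplitude share in `[0, 1]`.
#' @param t2_gauss,t2_exp Gaussian and exponential spin-spin times in
#'   microseconds; the rigid component must decay faster (`t2_gauss < t2_exp`).
#' @param times Sample times in microseconds, >= 0, strictly increasing.
#' @param noise_sd Additive Gaussian noise SD (amplitude units).
#' @param seed Integer RNG seed used when `noise_sd > 0`.
#' @return A validated `fid_spec` object.
#' @export
fid_spec <- function(m0 = 1, gaussian_fraction = 0.9,
                     t2_gauss = 10, t2_exp = 80,
                     times = seq(0, 500, by = 1), noise_sd = 0, seed = 1L) {
  check_number(m0, "m0", lower = 0, strict_lower = TRUE)
  check_number(gaussian_fraction, "gaussian_fraction", lower = 0, upper = 1)
  check_number(t2_gauss, "t2_gauss", lower = 0, strict_lower = TRUE)
  check_number(t2_exp, "t2_exp", lower = t2_gauss, strict_lower = TRUE)
  if (!is.numeric(times) || length(times) < 2L || any(times < 0)) {
    stop_invalid("`times` must be >= 0 with at least two points")
  }
  check_increasing(times, "times")
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(m0 = m0, gaussian_fraction = gaussian_fraction,
         t2_gauss = t2_gauss, t2_exp = t2_exp,
         times = as.numeric(times), noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "fid_spec"
  )
}

#' Generate a synthetic free-induction decay
#'
#' @param spec A [fid_spec()].
#' @return A tibble with columns `time_us` and `amplitude`; generating spec in
#'   the `ground_truth` attribute.
#' @examples
#' fid <- gen_fid(fid_spec(gaussian_fraction = 0.9, t2_gauss = 10, t2_exp = 80))
#' @export
gen_fid <- function(spec) {
  stopifnot(inherits(spec, "fid_spec"))
  amp <- fid_model(spec$times, spec$m0, spec$gaussian_fraction,
                   spec$t2_gauss, spec$t2_exp)
  if (spec$noise_sd > 0) {
    amp <- amp + with_seed_(spec$seed, rnorm(length(amp), 0, spec$noise_sd))
  }
  out <- tibble(time_us = spec$times, amplitude = amp)
  attr(out, "ground_truth") <- spec
  out
}

fid_model <- function(t, m0, f_g, t2g, t2e) {
  m0 * (f_g * exp(-t^2 / (2 * t2g^2)) + (1 - f_g) * exp(-t / t2e))
}

#' Specification of a synthetic T1-vs-temperature curve
#'
#' Describes spin-lattice relaxation produced by one or more thermally
#' activated motional processes. Each process contributes a rate
#' [bpp_rate()] with an Arrhenius correlation time [arrhenius_tau()]; rates
#' add, so \eqn{T_1(T) = 1/\sum_k R_k(T)}. Noise, when requested, is
#' multiplicative log-normal, reflecting the relative (percent-level) error
#' of relaxation-time measurements.
#'
#' @param processes Data frame with columns `c_constant` (s^-2), `tau0` (s),
#'   `ea` (kJ/mol), optionally `label`; see [relaxation_process()].
#' @param larmor_frequency Larmor frequency in Hz (not angular).
#' @param temperatures Temperatures in kelvin (> 0).
#' @param noise_relative_sd Relative SD of log-normal noise (0 = noiseless).
#' @param seed Integer RNG seed used when noise is on.
#' @return A validated `t1_curve_spec` object.
#' @export
t1_curve_spec <- function(processes, larmor_frequency = 25e6,
                          temperatures = seq(80, 300, by = 2),
                          noise_relative_sd = 0, seed = 1L) {
  processes <- as_process_table(processes)
  check_number(larmor_frequency, "larmor_frequency", lower = 0, strict_lower = TRUE)
  check_positive_vector(temperatures, "temperatures")
  check_number(noise_relative_sd, "noise_relative_sd", lower = 0)
  structure(
    list(processes = processes, larmor_frequency = larmor_frequency,
         temperatures = as.numeric(temperatures),
         noise_relative_sd = noise_relative_sd, seed = as.integer(seed)),
    class = "t1_curve_spec"
  )
}

#' Generate a synthetic T1(T) series
#'
#' @param spec A [t1_curve_spec()].
#' @return A tibble with `temperature_K` and `t1_s`, Larmor frequency in the
#'   `larmor_frequency` attribute and the spec in `ground_truth`.
#' @export
gen_t1_curve <- function(spec) {
  stopifnot(inherits(spec, "t1_curve_spec"))
  t1 <- t1_model(spec$temperatures, spec$processes,
                 2 * pi * spec$larmor_frequency)
  if (spec$noise_relative_sd > 0) {
    sdlog <- sqrt(log(1 + spec$noise_relative_sd^2))
    t1 <- t1 * with_seed_(spec$seed,
                          rlnorm(length(t1), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  out <- tibble(temperature_K = spec$temperatures, t1_s = t1)
  attr(out, "larmor_frequency") <- spec$larmor_frequency
  attr(out, "ground_truth") <- spec
  out
}

#' Specification of a synthetic diffraction peak set
#'
#' Each peak is generated with the width the Scherrer relation assigns to its
#' crystallite size: \eqn{\beta = K\lambda/(L\cos\theta)} (radians, converted
#' to degrees), the exact inverse of [scherrer_size()]. Used for round-trip
#' testing of the sizing analysis.
#'
#' @param peaks Data frame with columns `two_theta` (degrees, in (0, 180)) and
#'   `crystallite_size` (nm, > 0).
#' @param wavelength X-ray wavelength in angstroms (default Cu K-alpha).
#' @param scherrer_constant Dimensionless shape factor K.
#' @return A validated `peak_set_spec`.
#' @export
peak_set_spec <- function(peaks, wavelength = 1.54, scherrer_constant = 0.9) {
  if (!is.data.frame(peaks) ||
      !all(c("two_theta", "crystallite_size") %in% names(peaks))) {
    stop_invalid("`peaks` needs columns `two_theta` and `crystallite_size`")
  }
  if (any(peaks$two_theta <= 0) || any(peaks$two_theta >= 180)) {
    stop_invalid("`two_theta` must lie in (0, 180) degrees")
  }
  check_positive_vector(peaks$crystallite_size, "crystallite_size")
  check_number(wavelength, "wavelength", lower = 0, strict_lower = TRUE)
  check_number(scherrer_constant, "scherrer_constant", lower = 0, strict_lower = TRUE)
  structure(
    list(peaks = as_tibble(peaks[c("two_theta", "crystallite_size")]),
         wavelength = wavelength, scherrer_constant = scherrer_constant),
    class = "peak_set_spec"
  )
}

#' Generate diffraction peaks broadened per crystallite size
#'
#' @param spec A [peak_set_spec()].
#' @return A tibble with `two_theta` (deg), `fwhm` (deg) and `wavelength` (A).
#' @examples
#' gen_peaks(peak_set_spec(data.frame(
#'   two_theta = c(6.6, 16.4, 19.2, 22.4), crystallite_size = 40
#' )))
#' @export
gen_peaks <- function(spec) {
  stopifnot(inherits(spec, "peak_set_spec"))
  theta <- spec$peaks$two_theta / 2 * pi / 180
  # inverse Scherrer: width in radians, then to degrees; wavelength A -> nm
  beta_rad <- spec$scherrer_constant * (spec$wavelength / 10) /
    (spec$peaks$crystallite_size * cos(theta))
  out <- tibble(
    two_theta = spec$peaks$two_theta,
    fwhm = beta_rad * 180 / pi,
    wavelength = spec$wavelength
  )
  attr(out, "ground_truth") <- spec
  out
}
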