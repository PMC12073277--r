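# Multi-process spin-lattice relaxation: the Bloembergen-Purcell-Pound (BPP)
# spectral density with Arrhenius correlation times.
#
# One thermally activated motional process contributes the rate
#   1/T1 = C [ tau_c / (1 + w0^2 tau_c^2) + 4 tau_c / (1 + 4 w0^2 tau_c^2) ]
# with tau_c = tau0 exp(EA / RT). Rates of independent processes add, so
# T1(T) = 1 / sum_k rate_k(T). The rate is maximal (T1 minimal) at the
# universal point w0 * tau_c ~ 0.6158, independent of C, tau0 and EA.

#' Define a BPP relaxation process
#'
#' @param c_constant Relaxation constant C in s^-2 (> 0); proportional to the
#'   squared dipolar coupling of the protons participating in the motion.
#' @param tau0 Arrhenius pre-exponential (attempt) time in seconds (> 0).
#' @param ea Activation energy in kJ/mol (> 0).
#' @param label Optional name, conventionally one of `"low-temperature"`,
#'   `"intermediate"`, `"high-temperature"`.
#' @return A one-row tibble usable anywhere a process table is expected.
#' @examples
#' relaxation_process(5.7e7, 2.4e-11, 6.8, "intermediate")
#' @export
relaxation_process <- function(c_constant, tau0, ea, label = NA_character_) {
  check_number(c_constant, "c_constant", lower = 0, strict_lower = TRUE)
  check_number(tau0, "tau0", lower = 0, strict_lower = TRUE)
  check_number(ea, "ea", lower = 0, strict_lower = TRUE)
  tibble(c_constant = c_constant, tau0 = tau0, ea = ea, label = label)
}

# Coerce/validate a process table (data frame with c_constant, tau0, ea).
as_process_table <- function(processes) {
  if (!is.data.frame(processes) ||
      !all(c("c_constant", "tau0", "ea") %in% names(processes))) {
    stop_invalid("`processes` needs columns `c_constant`, `tau0`, `ea`")
  }
  if (nrow(processes) < 1L) stop_invalid("at least one relaxation process is required")
  check_positive_vector(processes$c_constant, "c_constant")
  check_positive_vector(processes$tau0, "tau0")
  check_positive_vector(processes$ea, "ea")
  out <- as_tibble(processes)
  if (!"label" %in% names(out)) out$label <- NA_character_
  out[c("c_constant", "tau0", "ea", "label")]
}

#' BPP spin-lattice relaxation rate
#'
#' Evaluates the single-process relaxation rate
#' \deqn{1/T_1 = C\left[\frac{\tau_c}{1+\omega_0^2\tau_c^2} +
#'   \frac{4\tau_c}{1+4\omega_0^2\tau_c^2}\right]}
#'
#' @param tau_c Correlation time(s) in seconds (> 0; `Inf` allowed, giving 0).
#' @param omega0 Larmor angular frequency in rad/s (> 0).
#' @param c_constant Relaxation constant C in s^-2.
#' @return Relaxation rate(s) 1/T1 in s^-1.
#' @examples
#' bpp_rate(1e-9, 2 * pi * 25e6, 5.7e7)
#' @export
bpp_rate <- function(tau_c, omega0, c_constant) {
  if (any(tau_c <= 0, na.rm = TRUE)) stop_invalid("`tau_c` must be positive")
  check_number(omega0, "omega0", lower = 0, strict_lower = TRUE)
  check_number(c_constant, "c_constant", lower = 0, strict_lower = TRUE)
  x <- omega0 * tau_c
  r <- c_constant * (tau_c / (1 + x^2) + 4 * tau_c / (1 + 4 * x^2))
  r[is.infinite(tau_c)] <- 0
  r
}

#' Arrhenius correlation time
#'
#' \eqn{\tau_c = \tau_0 \exp(E_A / RT)} with R = 8.314 J/(mol K).
#' Below the temperature where the exponent would overflow (~`ea * 1000 /
#' (8.314 * 700)` kelvin for double precision), `Inf` is returned rather than
#' an error, which downstream rate evaluation treats as a frozen process.
#'
#' @param temperature Temperature(s) in kelvin (> 0).
#' @param tau0 Pre-exponential time in seconds.
#' @param ea Activation energy in kJ/mol.
#' @return Correlation time(s) in seconds.
#' @examples
#' arrhenius_tau(160.5, 2.4e-11, 6.8)
#' @export
arrhenius_tau <- function(temperature, tau0, ea) {
  if (any(temperature <= 0)) stop_invalid("`temperature` must be positive kelvin")
  check_number(tau0, "tau0", lower = 0, strict_lower = TRUE)
  check_number(ea, "ea", lower = 0)
  expo <- ea * 1000 / (.R_GAS * temperature)
  out <- rep(Inf, length(expo))
  ok <- expo < 700
  out[ok] <- tau0 * exp(expo[ok])
  out
}

#' Multi-process T1 as a function of temperature
#'
#' Total relaxation rate is the sum over processes; `t1_model` returns its
#' reciprocal. A purely mathematical function of temperature: ascending and
#' descending grids give identical values (no hysteresis by construction).
#'
#' @param temperature Temperature(s) in kelvin.
#' @param processes Process table (see [relaxation_process()]).
#' @param omega0 Larmor angular frequency in rad/s.
#' @return T1 value(s) in seconds.
#' @export
t1_model <- function(temperature, processes, omega0) {
  processes <- as_process_table(processes)
  rate <- rep(0, length(temperature))
  for (k in seq_len(nrow(processes))) {
    tau <- arrhenius_tau(temperature, processes$tau0[k], processes$ea[k])
    rate <- rate + bpp_rate(tau, omega0, processes$c_constant[k])
  }
  1 / rate
}

# The universal reduced frequency x* = w0 * tau_c at the BPP rate maximum,
# found numerically once per call; x* ~ 0.6158 for any parameters.
bpp_xstar <- function() {
  optimize(function(x) x / (1 + x^2) + 4 * x / (1 + 4 * x^2),
           interval = c(0.1, 2), maximum = TRUE, tol = 1e-12)$maximum
}

#' Locate the T1 minimum of a single BPP process
#'
#' The rate maximum occurs at the universal reduced frequency
#' \eqn{\omega_0\tau_c \approx 0.6158} regardless of C, \eqn{\tau_0} or
#' \eqn{E_A}; inverting the Arrhenius law at \eqn{\tau_c^* = 0.6158/\omega_0}
#' gives the minimum temperature in closed form, and the rate there gives
#' the minimum T1.
#'
#' @param process One-row process table ([relaxation_process()]).
#' @param larmor_frequency Larmor frequency in Hz (not angular).
#' @return A one-row tibble: `t_min_K`, `t1_min_s`, `omega_tau` (the reduced
#'   frequency at the minimum) and `in_range` (`FALSE` when the minimum falls
#'   outside (1, 1e4) K, where the Arrhenius picture is meaningless).
#' @examples
#' t1_minimum(relaxation_process(5.7e7, 2.4e-11, 6.8), 25e6)
#' @export
t1_minimum <- function(process, larmor_frequency) {
  process <- as_process_table(process)
  if (nrow(process) != 1L) stop_invalid("`process` must be a single process")
  check_number(larmor_frequency, "larmor_frequency", lower = 0, strict_lower = TRUE)
  omega0 <- 2 * pi * larmor_frequency
  xstar <- bpp_xstar()
  tau_star <- xstar / omega0
  if (tau_star <= process$tau0) {
    stop_invalid("tau0 exceeds the correlation time at the minimum; no minimum at finite temperature")
  }
  t_min <- process$ea * 1000 / (.R_GAS * log(tau_star / process$tau0))
  t1_min <- 1 / bpp_rate(tau_star, omega0, process$c_constant)
  tibble(
    t_min_K = t_min,
    t1_min_s = t1_min,
    omega_tau = xstar,
    in_range = t_min > 1 && t_min < 1e4
  )
}
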