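# broom-style tidy()/glance() methods for the fitted objects.

#' Tidy a recovery fit
#'
#' @param x A `recovery_fit`.
#' @param ... Unused.
#' @return One row per component: `component`, `t1_s`, `fraction`.
#' @export
tidy.recovery_fit <- function(x, ...) {
  tibble(
    component = if (x$n_components == 2L) c("short", "long") else "mono",
    t1_s = x$t1,
    fraction = x$fractions
  )
}

#' @rdname tidy.recovery_fit
#' @export
glance.recovery_fit <- function(x, ...) {
  tibble(n_components = x$n_components, m0 = x$m0,
         residual_rms = x$residual_rms, aicc = x$aicc, converged = x$converged)
}

#' Tidy an FID decomposition
#'
#' @param x An `fid_fit`.
#' @param ... Unused.
#' @return One row per component: `component` (`"gaussian"` = rigid,
#'   `"exponential"` = mobile), `t2_us`, `fraction`.
#' @export
tidy.fid_fit <- function(x, ...) {
  tibble(
    component = c("gaussian", "exponential"),
    t2_us = c(x$t2_gauss, x$t2_exp),
    fraction = c(x$gaussian_fraction, 1 - x$gaussian_fraction)
  )
}

#' @rdname tidy.fid_fit
#' @export
glance.fid_fit <- function(x, ...) {
  tibble(m0 = x$m0, residual_rms = x$residual_rms, converged = x$converged)
}

#' Tidy a BPP fit
#'
#' @param x A `bpp_fit`.
#' @param ... Unused.
#' @return One row per process: label, mode, `c_constant` (s^-2), `tau0` (s),
#'   `ea` (kJ/mol) and standard errors.
#' @export
tidy.bpp_fit <- function(x, ...) {
  x$processes
}

#' @rdname tidy.bpp_fit
#' @export
glance.bpp_fit <- function(x, ...) {
  tibble(n_processes = nrow(x$processes), n_points = x$n_points,
         residual_log_rms = x$residual_log_rms,
         larmor_frequency = x$larmor_frequency, converged = x$converged)
}
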